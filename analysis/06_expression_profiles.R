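#!/usr/bin/env Rscript
# Developmental-stage expression: per-gene per-stage read counts and RPKM
# from the read placements, expressed-gene proportions per group and stage,
# and a Welch t-test comparing RPKM between groups.

source("analysis/00_config.R")

models <- read_gene_models_gff3(file.path(WORLD_DIR, "genes.gff3"))
reads <- read_placements(file.path(WORLD_DIR, "reads.tsv"))
labels <- read.delim(file.path(RESULTS_DIR, "labels.tsv"))

expr <- expression_matrix(models, reads, rpkm_threshold = 0)
write.table(expr, file.path(RESULTS_DIR, "expression.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

props <- stage_proportions(labels, expr, groups = c("SSG", "GSG", "EC"))
write.table(props, file.path(RESULTS_DIR, "proportions.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

message("mean proportion of expressed genes across stages:")
for (g in c("SSG", "GSG", "EC"))
  message(sprintf("  %-4s %.3f", g,
                  mean(props$proportion[props$group == g])))

# group contrast on per-gene mean RPKM
mean_rpkm <- tapply(expr$rpkm, expr$gene_id, mean)
lab_of <- setNames(labels$label, labels$gene_id)
by_grp <- split(as.numeric(mean_rpkm), lab_of[names(mean_rpkm)])
tt <- two_sample_ttest(by_grp$SSG, by_grp$GSG)
message(sprintf("Welch t-test, SSG vs GSG mean RPKM: t = %.3f, p = %.3g",
                tt$t, tt$p))
tt2 <- two_sample_ttest(by_grp$GSG, by_grp$EC)
message(sprintf("Welch t-test, GSG vs EC mean RPKM:  t = %.3f, p = %.3g",
                tt2$t, tt2$p))

truth <- read.delim(file.path(WORLD_DIR, "truth", "expression.tsv"))
m <- merge(expr, truth, by = c("gene_id", "stage"))
message(sprintf("per-stage expressed-flag agreement with truth: %.1f%%",
                100 * mean(m$expressed.x == m$expressed.y)))
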