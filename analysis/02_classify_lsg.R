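#!/usr/bin/env Rscript
# Hierarchical homology screen: every focal protein against the clade
# panels, labels SSG / GSG / EC at E <= 1e-5, then agreement with the
# planted truth.

source("analysis/00_config.R")

proteome <- read_protein_fasta(file.path(WORLD_DIR, "proteome.fa"))
panels <- load_panels(file.path(WORLD_DIR, "panels.yaml"))
message("classifying ", length(proteome), " proteins against panels: ",
        paste(names(panels), collapse = ", "))

cls <- classify_proteome(proteome, panels, cutoff = 1e-5)
write.table(cls$labels, file.path(RESULTS_DIR, "labels.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

message("counts: SSG ", cls$counts[["SSG"]], ", GSG ", cls$counts[["GSG"]],
        ", EC ", cls$counts[["EC"]])

truth <- read.delim(file.path(WORLD_DIR, "truth", "genes.tsv"))
m <- merge(cls$labels[, c("gene_id", "label")],
           truth[, c("gene_id", "class")], by = "gene_id")
agree <- mean(m$label == m$class)
message(sprintf("agreement with planted truth: %.1f%% (%d/%d)",
                100 * agree, sum(m$label == m$class), nrow(m)))
if (agree < 1)
  print(m[m$label != m$class, ])
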