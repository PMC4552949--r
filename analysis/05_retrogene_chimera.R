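#!/usr/bin/env Rscript
# Retrogene and chimera screen: six-frame translated matching of the
# proteome onto the genome, merging of adjacent matches (<40 bp), identity
# and length filtering, parental assignment among multi-exon proteins,
# intron-aware verification (+/-10 kb flanks), then CDS-overlap chimera
# calls (>50 bp, flagged above 90 bp).

source("analysis/00_config.R")

genome <- read_genome_fasta(file.path(WORLD_DIR, "genome.fa"))
models <- read_gene_models_gff3(file.path(WORLD_DIR, "genes.gff3"))
proteome <- read_protein_fasta(file.path(WORLD_DIR, "proteome.fa"))

message("screening ", length(proteome), " proteins against ",
        nchar(genome[[1]]), " nt of genome (six frames)")
retro <- call_retrogenes(proteome, genome, models)
write.table(retro, file.path(RESULTS_DIR, "retrogenes.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
if (nrow(retro))
  write_bed_track(retro[, c("chrom", "start", "end")],
                  file.path(RESULTS_DIR, "retro_loci.bed"))
message("accepted retrogene calls: ", nrow(retro))
print(retro[, c("retro_id", "start", "end", "parent_id",
                "spliced_align_score", "introns_in_match", "coverage")],
      row.names = FALSE)

chim <- call_chimeras(retro, models)
write.table(chim, file.path(RESULTS_DIR, "chimeras.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
message("chimeric genes: ", nrow(chim))
if (nrow(chim)) print(chim, row.names = FALSE)

truth <- read.delim(file.path(WORLD_DIR, "truth", "retro.tsv"))
recovered <- sum(vapply(seq_len(nrow(truth)), function(i)
  any(retro$parent_id == truth$parent_id[i] &
        retro$start <= truth$end[i] & retro$end >= truth$start[i]),
  logical(1)))
message(sprintf("planted retro loci recovered: %d/%d; false calls: %d",
                recovered, nrow(truth), nrow(retro) - recovered))
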