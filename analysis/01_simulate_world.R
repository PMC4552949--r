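#!/usr/bin/env Rscript
# Simulate the synthetic study world: a miniature genome with planted
# species-specific, genus-specific and conserved genes, clade-stratified
# homolog panels, TE/paralog annotation tracks, retrocopies, one chimeric
# host, transcript mappings and stage-resolved read placements.

source("analysis/00_config.R")

cfg <- analysis_world_config()
world <- generate_world(cfg, WORLD_DIR)

message("world written to ", WORLD_DIR)
message("genome: ", nchar(world$genome), " nt on ", world$chrom)
message("annotated genes: ", nrow(world$models$genes),
        " (", paste(names(table(world$truth$genes$class)),
                    table(world$truth$genes$class),
                    sep = "=", collapse = ", "), ")")
message("planted retro loci: ", nrow(world$truth$retro),
        " of which chimera-attached: ",
        sum(!is.na(world$truth$retro$chimeric_host)))
message("TE track: ", nrow(world$te_track), " intervals; paralog track: ",
        nrow(world$paralog_track))
message("transcripts: ", length(world$transcripts),
        " (incl. planted filter/ambiguity decoys)")
message("read placements: ", nrow(world$reads), " over ",
        length(unique(world$reads$stage)), " stages")
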