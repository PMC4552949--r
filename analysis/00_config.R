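# Shared settings for the analysis scripts. Everything downstream of the
# simulated world lives under results/.

library(lsgscan)

ANALYSIS_SEED <- 11L
RESULTS_DIR <- "results"
WORLD_DIR <- file.path(RESULTS_DIR, "world")

# Desk-scale study conditions: three gene classes sized to echo the
# published group contrasts, two proteomes per clade panel, a 60 kb contig,
# two free retrocopies and one chimeric host.
analysis_world_config <- function(seed = ANALYSIS_SEED) {
  world_config(
    seed = seed,
    n_genes_per_class = c(SSG = 5L, GSG = 5L, EC = 5L),
    n_species_per_clade = c(congeners = 2L, other_nematodes = 2L,
                            invertebrates = 2L, vertebrates = 2L),
    genome_size = 60000L, n_retrogenes = 2L, n_chimeras = 1L,
    decoys_per_species = 1L)
}

dir.create(RESULTS_DIR, showWarnings = FALSE)
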