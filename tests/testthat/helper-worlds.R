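# Shared synthetic worlds, built once per test run and cached.

.world_cache <- new.env(parent = emptyenv())

small_world_config <- function(seed = 11L) {
  world_config(
    seed = seed,
    n_genes_per_class = c(SSG = 5L, GSG = 5L, EC = 5L),
    n_species_per_clade = c(congeners = 2L, other_nematodes = 2L,
                            invertebrates = 2L, vertebrates = 2L),
    genome_size = 60000L, n_retrogenes = 2L, n_chimeras = 1L,
    decoys_per_species = 1L)
}

# default (divergent-homolog) world
small_world <- function() {
  if (is.null(.world_cache$small))
    .world_cache$small <- generate_world(small_world_config())
  .world_cache$small
}

# exact-homology limit: zero mutation everywhere, verbatim retrocopies
zero_world <- function() {
  if (is.null(.world_cache$zero)) {
    cfg <- small_world_config(seed = 7L)
    cfg$mutation_rates[] <- 0
    cfg$retro_divergence <- 0
    .world_cache$zero <- generate_world(cfg)
  }
  .world_cache$zero
}

world_genome <- function(w) stats::setNames(w$genome, w$chrom)

# cached full retrogene screens (the most expensive stage)
retro_calls_for <- function(which = c("small", "zero")) {
  which <- match.arg(which)
  key <- paste0("retro_", which)
  if (is.null(.world_cache[[key]])) {
    w <- if (which == "small") small_world() else zero_world()
    .world_cache[[key]] <- call_retrogenes(w$proteome, world_genome(w),
                                           w$models)
  }
  .world_cache[[key]]
}

# cached proteome classification of the zero-mutation world
zero_classification <- function() {
  if (is.null(.world_cache$zero_cls)) {
    w <- zero_world()
    .world_cache$zero_cls <- classify_proteome(w$proteome, w$panels)
  }
  .world_cache$zero_cls
}
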