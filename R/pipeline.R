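#' Pipeline thresholds, all in one auditable place
#'
#' Every numeric cutoff of the analysis with its default: homology E-value
#' 1e-5; translated-search E-value 1e-3; length-class bounds (30, 70); merge
#' gap 40 bp; merged-match identity 0.30 and minimum length 50 aa;
#' spliced-alignment minimum score 35; minimum parental introns 2; parental
#' coverage 0.40; chimera CDS overlap 50 bp with false-positive flag at 90
#' bp; verification flank 10,000 bp; mapping filters (150 bp, 98%, 97%,
#' 75%); mapping ambiguity 2%; EST overlap 100 bp; RPKM threshold 0; origin
#' containment threshold 1.0.
#'
#' @param ... Named overrides of any default.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    homology_evalue = 1e-5,
    translated_evalue = 1e-3,
    length_class_bounds = c(30L, 70L),
    merge_gap_bp = 40L,
    merged_min_identity = 0.30,
    merged_min_aa = 50L,
    spliced_min_score = 35,
    min_introns = 2L,
    min_parent_coverage = 0.40,
    chimera_overlap_bp = 50L,
    chimera_fp_bp = 90L,
    flank_bp = 10000L,
    map_min_length = 150L,
    map_min_identity = 98,
    map_min_cov_mapping = 97,
    map_min_cov_whole = 75,
    ambiguity_rel_tol = 0.02,
    est_overlap_bp = 100L,
    rpkm_threshold = 0,
    containment_threshold = 1.0
  )
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config fields: ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  stopifnot(cfg$homology_evalue > 0, cfg$translated_evalue > 0,
            cfg$merge_gap_bp >= 0, cfg$merged_min_identity >= 0,
            cfg$merged_min_identity <= 1, cfg$min_parent_coverage >= 0,
            cfg$min_parent_coverage <= 1, cfg$containment_threshold > 0,
            cfg$containment_threshold <= 1, cfg$ambiguity_rel_tol >= 0)
  structure(cfg, class = "pipeline_config")
}

#' Hash of a pipeline configuration
#'
#' MD5 of the canonical YAML serialization; changes iff any threshold
#' changes. The same serialization is used for the lossless config
#' round-trip in the run manifest.
#'
#' @param config A [pipeline_config()].
#' @return MD5 hex string.
#' @export
config_hash <- function(config) {
  f <- tempfile(fileext = ".yaml")
  on.exit(unlink(f))
  yaml::write_yaml(unclass(config)[order(names(config))], f)
  unname(tools::md5sum(f))
}

.log_stage <- function(quiet, fmt, ...) {
  if (!quiet) message(sprintf(fmt, ...))
}

#' Run the full analysis end-to-end
#'
#' Either consumes an input directory laid out like [generate_world()]
#' output (genome.fa, genes.gff3, proteome.fa, panels.yaml, te.bed,
#' paralogs.bed, mappings.tsv, reads.tsv) or, with `synthetic_seed` set,
#' generates a synthetic world first. Writes `labels.tsv`, `table1.tsv`,
#' `table1_anova.tsv`, `table2.tsv`, `retrogenes.tsv`, `chimeras.tsv`,
#' `retro_loci.bed`, `expression.tsv`, `proportions.tsv` and a
#' `manifest.yaml` carrying the config hash and seed. Identical inputs and
#' config give identical outputs.
#'
#' @param out_dir Result directory (created).
#' @param input_dir Directory with the input files (ignored in synthetic
#'   mode).
#' @param synthetic_seed If non-NULL, generate the inputs with
#'   [generate_world()] at this seed.
#' @param world_cfg Optional [world_config()] for synthetic mode (its seed
#'   is overridden by `synthetic_seed`).
#' @param config A [pipeline_config()].
#' @param quiet Suppress per-stage logging.
#' @return Invisibly, a list with the main result tables and the manifest.
#' @export
run_pipeline <- function(out_dir, input_dir = NULL, synthetic_seed = NULL,
                         world_cfg = NULL, config = pipeline_config(),
                         quiet = FALSE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(synthetic_seed)) {
    if (is.null(world_cfg)) world_cfg <- world_config(seed = synthetic_seed)
    else world_cfg$seed <- as.integer(synthetic_seed)
    input_dir <- file.path(out_dir, "world")
    .log_stage(quiet, "generating synthetic world (seed %d)", world_cfg$seed)
    generate_world(world_cfg, input_dir)
  }
  if (is.null(input_dir)) stop("either input_dir or synthetic_seed is required")
  need <- c("genome.fa", "genes.gff3", "proteome.fa", "panels.yaml",
            "te.bed", "paralogs.bed", "mappings.tsv", "reads.tsv")
  for (f in need)
    if (!file.exists(file.path(input_dir, f)))
      stop("missing input file: ", file.path(input_dir, f))

  genome <- read_genome_fasta(file.path(input_dir, "genome.fa"))
  models <- read_gene_models_gff3(file.path(input_dir, "genes.gff3"))
  proteome <- read_protein_fasta(file.path(input_dir, "proteome.fa"))
  panels <- load_panels(file.path(input_dir, "panels.yaml"))
  te_track <- read_bed_track(file.path(input_dir, "te.bed"))
  paralog_track <- read_bed_track(file.path(input_dir, "paralogs.bed"))
  mappings <- read_mapping_table(file.path(input_dir, "mappings.tsv"))
  reads <- read_placements(file.path(input_dir, "reads.tsv"))

  # -- classification
  .log_stage(quiet, "classifying %d proteins against %d panels",
             length(proteome), length(panels))
  cls <- classify_proteome(proteome, panels, cutoff = config$homology_evalue)
  .log_stage(quiet, "labels: SSG %d, GSG %d, EC %d",
             cls$counts[["SSG"]], cls$counts[["GSG"]], cls$counts[["EC"]])
  .write_tsv(cls$labels, file.path(out_dir, "labels.tsv"))

  # -- transcript mappings -> EST support
  filt <- filter_mappings(mappings, config$map_min_length,
                          config$map_min_identity, config$map_min_cov_mapping,
                          config$map_min_cov_whole)
  .log_stage(quiet, "mapping filters: %d in, %d pass", nrow(mappings),
             nrow(filt))
  retained <- resolve_ambiguous(filt, config$ambiguity_rel_tol)
  .log_stage(quiet, "ambiguity resolution: %d retained", nrow(retained))
  support <- stats::setNames(vapply(seq_len(nrow(models$genes)), function(i)
    est_expressed(models$genes[i, ], retained, config$est_overlap_bp),
    logical(1)), models$genes$gene_id)

  # -- characterization (Table 1 shape)
  feats <- feature_table(models, genome, proteome)
  gs <- group_feature_stats(feats, cls$labels, transcript_support = support)
  t1 <- gs$stats
  t1$transcript_pct <- gs$transcript_pct[t1$group]
  .write_tsv(t1, file.path(out_dir, "table1.tsv"))
  .write_tsv(gs$anova, file.path(out_dir, "table1_anova.tsv"))

  # -- origins (Table 2 shape)
  origin_calls <- call_origins(models, te_track, paralog_track,
                               config$containment_threshold)
  t2 <- list()
  for (g in c("SSG", "GSG")) {
    ids <- cls$labels$gene_id[cls$labels$label == g]
    tab <- tabulate_origins(
      origin_calls[origin_calls$gene_id %in% ids, , drop = FALSE],
      group_total = length(ids))
    tab$group <- g
    t2[[g]] <- tab
  }
  t2 <- do.call(rbind, t2)
  rownames(t2) <- NULL
  .write_tsv(t2, file.path(out_dir, "table2.tsv"))
  .log_stage(quiet, "origin union: SSG %d, GSG %d",
             t2$count[t2$group == "SSG" & t2$mechanism == "Total"],
             t2$count[t2$group == "GSG" & t2$mechanism == "Total"])

  # -- retrogene / chimera screen
  .log_stage(quiet, "retrogene screen over %d proteins", length(proteome))
  retro <- call_retrogenes(
    proteome, genome, models,
    evalue_cutoff = config$translated_evalue, max_gap = config$merge_gap_bp,
    min_identity = config$merged_min_identity,
    min_aa_length = config$merged_min_aa,
    min_score = config$spliced_min_score, min_introns = config$min_introns,
    min_coverage = config$min_parent_coverage, flank_bp = config$flank_bp)
  .log_stage(quiet, "retrogenes accepted: %d", nrow(retro))
  .write_tsv(retro, file.path(out_dir, "retrogenes.tsv"))
  if (nrow(retro))
    write_bed_track(retro[, c("chrom", "start", "end")],
                    file.path(out_dir, "retro_loci.bed"))
  else
    file.create(file.path(out_dir, "retro_loci.bed"))
  chim <- call_chimeras(retro, models, min_overlap = config$chimera_overlap_bp,
                        fp_overlap = config$chimera_fp_bp)
  .log_stage(quiet, "chimeric genes: %d", nrow(chim))
  .write_tsv(chim, file.path(out_dir, "chimeras.tsv"))

  # -- expression
  expr <- expression_matrix(models, reads,
                            rpkm_threshold = config$rpkm_threshold)
  .write_tsv(expr, file.path(out_dir, "expression.tsv"))
  props <- stage_proportions(cls$labels, expr,
                             groups = c("SSG", "GSG", "EC"),
                             rpkm_threshold = config$rpkm_threshold)
  .write_tsv(props, file.path(out_dir, "proportions.tsv"))

  manifest <- list(config_hash = config_hash(config),
                   seed = if (is.null(synthetic_seed)) NA
                   else as.integer(synthetic_seed),
                   n_proteins = length(proteome),
                   n_genes = nrow(models$genes),
                   config = unclass(config))
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  invisible(list(labels = cls$labels, counts = cls$counts, table1 = t1,
                 anova = gs$anova, table2 = t2, retrogenes = retro,
                 chimeras = chim, expression = expr, proportions = props,
                 est_support = support, manifest = manifest))
}
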