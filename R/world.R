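#' Configuration of a synthetic nematode world
#'
#' Builds and validates the parameter set for [generate_world()]. The
#' generator plants genes of three homology classes — species-specific (SSG),
#' genus-specific (GSG) and evolutionarily conserved (EC) — on a random
#' genome, together with clade-stratified homolog panels, TE and paralog
#' annotation tracks, intronless retrocopies of multi-exon parents, chimeric
#' host genes, transcript mappings and stage-resolved read placements, and
#' records the ground truth for every planted label.
#'
#' Defaults mirror the *C. elegans* study conditions: protein-length and
#' exon-count ranges per class bracket the published group means (SSG ~142 aa
#' / ~3 exons, GSG ~282 aa / ~4.5, EC ~500 aa / ~7.5), transcript-support
#' prevalences are 32.04% / 58.69% / 80.97%, and the fourteen developmental
#' stages run from 1-cell embryo to adult male. Per-clade amino-acid
#' substitution rates are non-decreasing with clade distance so that homology
#' detectability decays with divergence.
#'
#' @param seed Integer RNG seed; the same seed yields byte-identical output.
#' @param n_genes_per_class Named counts `c(SSG=, GSG=, EC=)` of planted genes.
#' @param n_species_per_clade Named counts of proteomes per panel
#'   (`congeners`, `other_nematodes`, `invertebrates`, `vertebrates`).
#' @param mutation_rates Per-clade amino-acid substitution probability in
#'   \[0,1\], non-decreasing in the order congener, other_nematode,
#'   invertebrate, vertebrate.
#' @param genome_size Contig length in nt (default 500 kb).
#' @param te_density TE insertions per 10 kb of genome.
#' @param n_retrogenes,n_chimeras Counts of planted free retrocopies and of
#'   retrocopies overlapping an annotated host gene.
#' @param protein_length_range,exon_count_range Per-class integer ranges
#'   (named lists of `c(min, max)`).
#' @param intron_length_range Intron length range in nt.
#' @param te_origin_frac,dup_origin_frac Probability that a planted SSG/GSG
#'   is fully contained in a TE / paralog annotation.
#' @param expressed_prevalence Per-class probability that a gene is expressed
#'   (drives both transcript support and read coverage).
#' @param stage_expression_profile Named mean read count per expressed gene
#'   at each developmental stage.
#' @param retro_divergence Amino-acid divergence of retrocopies from their
#'   parent (0 = verbatim CDS copy).
#' @param chimera_overlap_bp CDS overlap (nt) between a chimeric host gene
#'   and its retrocopy.
#' @param decoys_per_species Unrelated random proteins added to every panel
#'   proteome.
#' @param read_length Read length (nt) for placed reads.
#' @param n_background_reads Intergenic reads per stage (library-size
#'   padding; they overlap no gene).
#' @return A validated list of class `world_config`.
#' @export
world_config <- function(seed = 1L,
                         n_genes_per_class = c(SSG = 8L, GSG = 8L, EC = 8L),
                         n_species_per_clade = c(congeners = 3L,
                                                 other_nematodes = 3L,
                                                 invertebrates = 3L,
                                                 vertebrates = 3L),
                         mutation_rates = c(congener = 0.05,
                                            other_nematode = 0.15,
                                            invertebrate = 0.30,
                                            vertebrate = 0.45),
                         genome_size = 500000L,
                         te_density = 2,
                         n_retrogenes = 2L,
                         n_chimeras = 1L,
                         protein_length_range = list(SSG = c(100L, 180L),
                                                     GSG = c(220L, 340L),
                                                     EC  = c(400L, 600L)),
                         exon_count_range = list(SSG = c(1L, 3L),
                                                 GSG = c(2L, 5L),
                                                 EC  = c(5L, 9L)),
                         intron_length_range = c(50L, 300L),
                         te_origin_frac = 0.3,
                         dup_origin_frac = 0.3,
                         expressed_prevalence = c(SSG = 0.3204,
                                                  GSG = 0.5869,
                                                  EC  = 0.8097),
                         stage_expression_profile = NULL,
                         retro_divergence = 0.02,
                         chimera_overlap_bp = 70L,
                         decoys_per_species = 2L,
                         read_length = 75L,
                         n_background_reads = 50L) {
  if (is.null(stage_expression_profile))
    stage_expression_profile <- stats::setNames(rep(20, length(STAGE_NAMES)),
                                                STAGE_NAMES)
  cfg <- list(seed = as.integer(seed),
              n_genes_per_class = n_genes_per_class,
              n_species_per_clade = n_species_per_clade,
              mutation_rates = mutation_rates,
              genome_size = as.integer(genome_size),
              te_density = te_density,
              n_retrogenes = as.integer(n_retrogenes),
              n_chimeras = as.integer(n_chimeras),
              protein_length_range = protein_length_range,
              exon_count_range = exon_count_range,
              intron_length_range = intron_length_range,
              te_origin_frac = te_origin_frac,
              dup_origin_frac = dup_origin_frac,
              expressed_prevalence = expressed_prevalence,
              stage_expression_profile = stage_expression_profile,
              retro_divergence = retro_divergence,
              chimera_overlap_bp = as.integer(chimera_overlap_bp),
              decoys_per_species = as.integer(decoys_per_species),
              read_length = as.integer(read_length),
              n_background_reads = as.integer(n_background_reads))
  validate_world_config(cfg)
  structure(cfg, class = "world_config")
}

#' Developmental stages profiled by the expression module
#' @export
STAGE_NAMES <- c("1-cell", "2-cell", "4-cell", "28-cell",
                 "early embryo", "late embryo",
                 "L1", "L2", "L3", "L4", "L4 male",
                 "young adult", "adult hermaphrodite", "adult male")

validate_world_config <- function(cfg) {
  stopifnot(all(c("SSG", "GSG", "EC") %in% names(cfg$n_genes_per_class)))
  if (any(cfg$n_genes_per_class < 0) || any(cfg$n_species_per_clade < 0) ||
      cfg$n_retrogenes < 0 || cfg$n_chimeras < 0)
    stop("configuration error: all counts must be >= 0")
  mr <- cfg$mutation_rates[c("congener", "other_nematode",
                             "invertebrate", "vertebrate")]
  if (any(is.na(mr)) || any(mr < 0) || any(mr > 1))
    stop("configuration error: mutation rates must lie in [0,1]")
  if (any(diff(mr) < 0))
    stop("configuration error: mutation rates must be non-decreasing with clade distance")
  # every retrocopy needs its own multi-exon (>= 3 exon) parent
  n_inserts <- cfg$n_retrogenes + cfg$n_chimeras
  if (n_inserts > 0) {
    ec_range <- cfg$exon_count_range$EC
    if (cfg$n_genes_per_class[["EC"]] < n_inserts || ec_range[2] < 3)
      stop("configuration error: more retrogenes/chimeras than available multi-exon EC parents")
  }
  if (cfg$chimera_overlap_bp < 1)
    stop("configuration error: chimera_overlap_bp must be positive")
  invisible(cfg)
}

# ---- sequence helpers -------------------------------------------------------

.BG_BASE_PROB <- c(A = 0.32, C = 0.18, G = 0.18, T = 0.32)

random_dna <- function(n) {
  if (n <= 0) return("")
  paste(sample(names(.BG_BASE_PROB), n, replace = TRUE, prob = .BG_BASE_PROB),
        collapse = "")
}

random_protein <- function(len) {
  paste0("M", paste(sample(.AA_STANDARD, len - 1L, replace = TRUE),
                    collapse = ""))
}

#' Mutate a protein under a uniform substitution model
#'
#' Each residue is independently replaced, with probability `rate`, by a
#' uniformly chosen different amino acid. No indels.
#'
#' @param seq Amino-acid string.
#' @param rate Substitution probability per site in \[0,1\].
#' @return The mutated string.
#' @export
mutate_protein <- function(seq, rate) {
  if (rate <= 0) return(seq)
  aa <- strsplit(seq, "")[[1]]
  hit <- stats::runif(length(aa)) < rate
  if (any(hit))
    aa[hit] <- vapply(aa[hit],
                      function(x) sample(setdiff(.AA_STANDARD, x), 1L),
                      character(1))
  paste(aa, collapse = "")
}

# reverse-translation table (stop codons excluded)
.codons_by_aa <- local({
  gc <- Biostrings::GENETIC_CODE
  split(names(gc), gc)[setdiff(unique(gc), "*")]
})

reverse_translate <- function(protein) {
  aa <- strsplit(protein, "")[[1]]
  paste(vapply(aa, function(x) sample(.codons_by_aa[[x]], 1L), character(1)),
        collapse = "")
}

# Mutate a CDS at the codon level: selected codons are re-encoded for a
# different amino acid; untouched codons stay verbatim (rate 0 => identity).
mutate_cds_codons <- function(cds, rate) {
  if (rate <= 0) return(cds)
  n_codon <- nchar(cds) %/% 3L
  hit <- which(stats::runif(n_codon) < rate)
  if (!length(hit)) return(cds)
  codons <- substring(cds, 3L * (seq_len(n_codon) - 1L) + 1L,
                      3L * seq_len(n_codon))
  gc <- Biostrings::GENETIC_CODE
  for (i in hit) {
    old_aa <- gc[[codons[i]]]
    new_aa <- sample(setdiff(.AA_STANDARD, old_aa), 1L)
    codons[i] <- sample(.codons_by_aa[[new_aa]], 1L)
  }
  paste(codons, collapse = "")
}

# Split n_codons into k exon blocks of >= min_codons codons each (codon-
# aligned junctions). Returns codon counts per exon.
split_codons <- function(n_codons, k, min_codons = 10L) {
  if (k == 1L) return(n_codons)
  if (n_codons < k * min_codons)
    stop("CDS too short for ", k, " exons")
  extra <- n_codons - k * min_codons
  # random composition of `extra` over k parts
  cuts <- sort(sample.int(extra + k - 1L, k - 1L))
  parts <- diff(c(0L, cuts, extra + k)) - 1L
  parts + min_codons
}

# ---- gene design ------------------------------------------------------------

# A designed gene: protein, CDS, exon codon blocks, intron sequences, and the
# assembled genomic sequence with exon offsets (1-based, relative to gene
# start).
design_gene <- function(gene_id, class, cfg) {
  plen_r <- cfg$protein_length_range[[class]]
  elen_r <- cfg$exon_count_range[[class]]
  plen <- sample(seq.int(plen_r[1], plen_r[2]), 1L)
  k <- sample(seq.int(elen_r[1], elen_r[2]), 1L)
  protein <- random_protein(plen)
  cds <- reverse_translate(protein)
  exon_codons <- split_codons(plen, k)
  exon_nt <- 3L * exon_codons
  introns <- if (k > 1L)
    vapply(seq_len(k - 1L), function(i)
      random_dna(sample(seq.int(cfg$intron_length_range[1],
                                cfg$intron_length_range[2]), 1L)),
      character(1))
  else character(0)
  # assemble
  pieces <- character(2L * k - 1L)
  exon_start <- integer(k); off <- 0L
  cds_off <- cumsum(c(0L, exon_nt))
  for (i in seq_len(k)) {
    exon_start[i] <- off + 1L
    pieces[2L * i - 1L] <- substr(cds, cds_off[i] + 1L, cds_off[i + 1L])
    off <- off + exon_nt[i]
    if (i < k) {
      pieces[2L * i] <- introns[i]
      off <- off + nchar(introns[i])
    }
  }
  list(gene_id = gene_id, class = class, protein = protein, cds = cds,
       exon_codons = exon_codons,
       exon_start = exon_start, exon_end = exon_start + exon_nt - 1L,
       seq = paste(pieces, collapse = ""), length = off)
}

# ---- retrogene planting -----------------------------------------------------

#' Spliced CDS of a gene model extracted from a genome
#'
#' @param genome A `DNAString` (or character) contig.
#' @param gene_id Gene identifier.
#' @param models A `gene_models` object (see [gene_models()]).
#' @return The concatenated exonic sequence as a character string.
#' @export
spliced_cds <- function(genome, gene_id, models) {
  ex <- models$exons[models$exons$gene_id == gene_id, , drop = FALSE]
  if (!nrow(ex)) stop("unknown gene: ", gene_id)
  ex <- ex[order(ex$start), ]
  g <- as.character(genome)
  paste(substring(g, ex$start, ex$end), collapse = "")
}

#' Plant an intronless retrocopy of a multi-exon parent into a genome
#'
#' Inserts the parent's spliced CDS (optionally mutated at the codon level)
#' into the genome at position `at` (default: appended at the contig end).
#' Parents with fewer than 3 exons are rejected: a retrocopy must be able to
#' carry at least two parental intron positions inside any substantial match.
#'
#' @param genome A `DNAString` or character contig.
#' @param parent_id Identifier of the parent gene within `models`.
#' @param models A [gene_models()] object containing the parent.
#' @param at Insertion point: the retro sequence is inserted *after* genomic
#'   position `at` (0 prepends; default = contig length, i.e. append).
#' @param mutation_rate Codon-level amino-acid divergence of the copy.
#' @return A list with `genome` (updated character string) and `retro_locus`
#'   (`c(start, end)`, 1-based inclusive coordinates of the insert).
#' @export
plant_retrogene <- function(genome, parent_id, models, at = NULL,
                            mutation_rate = 0) {
  ex <- models$exons[models$exons$gene_id == parent_id, , drop = FALSE]
  if (nrow(ex) < 3L)
    stop("parent must have >= 3 exons, got ", nrow(ex))
  g <- as.character(genome)
  if (is.null(at)) at <- nchar(g)
  stopifnot(at >= 0, at <= nchar(g))
  cds <- spliced_cds(g, parent_id, models)
  insert <- mutate_cds_codons(cds, mutation_rate)
  new_g <- paste0(substr(g, 1L, at), insert,
                  substr(g, at + 1L, nchar(g)))
  list(genome = new_g,
       retro_locus = c(start = at + 1L, end = at + nchar(insert)))
}

# ---- gene model container ---------------------------------------------------

#' Gene models on a genome
#'
#' A lightweight container pairing a per-gene table (span, strand, exon
#' count) with a per-exon interval table, both in 1-based inclusive
#' coordinates.
#'
#' @param genes data.frame with columns gene_id, chrom, strand, start, end,
#'   exon_count.
#' @param exons data.frame with columns gene_id, start, end.
#' @return An object of class `gene_models`.
#' @export
gene_models <- function(genes, exons) {
  stopifnot(all(c("gene_id", "chrom", "strand", "start", "end") %in%
                  names(genes)),
            all(c("gene_id", "start", "end") %in% names(exons)))
  structure(list(genes = genes, exons = exons), class = "gene_models")
}

#' @export
print.gene_models <- function(x, ...) {
  cat("gene_models:", nrow(x$genes), "genes,", nrow(x$exons), "exons\n")
  invisible(x)
}

genes_granges <- function(models) {
  g <- models$genes
  GenomicRanges::GRanges(g$chrom, IRanges::IRanges(g$start, g$end),
                         strand = g$strand, gene_id = g$gene_id)
}

exons_granges <- function(models) {
  e <- models$exons
  chrom <- models$genes$chrom[match(e$gene_id, models$genes$gene_id)]
  GenomicRanges::GRanges(chrom, IRanges::IRanges(e$start, e$end),
                         gene_id = e$gene_id)
}

# ---- world assembly ---------------------------------------------------------

#' Generate a synthetic world with planted ground truth
#'
#' Designs every gene, homolog panel, annotation track, retrocopy, transcript
#' and read placement in memory, deterministically from `config$seed`, and
#' (optionally) writes the standard-format files to `out_dir`:
#' `genome.fa`, `genes.gff3`, `proteome.fa`, `panels/<clade>_<species>.fa`,
#' `panels/outgroup_proteins.fa`, `te.bed`, `paralogs.bed`, `transcripts.fa`,
#' `mappings.tsv`, `reads.tsv`, and `truth/*.tsv`.
#'
#' @param config A [world_config()].
#' @param out_dir Output directory (created if needed); `NULL` keeps the
#'   world in memory only.
#' @return A list of class `synthetic_world` with elements `config`,
#'   `genome` (character), `models` ([gene_models()]), `proteome` (named
#'   character), `panels` (clade -> species -> named character), `te_track`
#'   and `paralog_track` (data.frames chrom/start/end, 1-based inclusive),
#'   `transcripts`, `mappings`, `reads`, `truth` (list of `genes`, `retro`,
#'   `expression` data.frames) and, when written, `dir`.
#' @export
generate_world <- function(config, out_dir = NULL) {
  validate_world_config(config)
  set.seed(config$seed)
  chrom <- "chrI"
  cls_counts <- config$n_genes_per_class

  # -- design annotated genes
  designs <- list()
  for (cls in c("SSG", "GSG", "EC")) {
    n <- cls_counts[[cls]]
    if (n > 0)
      for (i in seq_len(n))
        designs[[length(designs) + 1L]] <-
          design_gene(sprintf("gene_%s_%02d", cls, i), cls, config)
  }

  # -- retro inserts (free + chimera-attached), each with a distinct EC parent
  ec_ids <- vapply(Filter(function(d) d$class == "EC", designs),
                   `[[`, character(1), "gene_id")
  multi <- vapply(designs, function(d)
    d$class == "EC" && length(d$exon_start) >= 3L, logical(1))
  eligible <- vapply(designs[multi], `[[`, character(1), "gene_id")
  n_inserts <- config$n_retrogenes + config$n_chimeras
  if (n_inserts > length(eligible))
    stop("configuration error: more retrogenes/chimeras than available multi-exon EC parents")
  parents <- if (n_inserts > 0) sample(eligible, n_inserts) else character(0)
  design_by_id <- stats::setNames(designs,
                                  vapply(designs, `[[`, character(1), "gene_id"))
  retro_seqs <- lapply(parents, function(p)
    mutate_cds_codons(design_by_id[[p]]$cds, config$retro_divergence))

  # -- chimera host genes (single-exon, SSG-like: no homologs anywhere)
  chim_hosts <- list()
  if (config$n_chimeras > 0) {
    for (i in seq_len(config$n_chimeras)) {
      host_cfg <- config
      # host needs a first exon longer than the planted CDS overlap
      min_len <- max(config$protein_length_range$SSG[1],
                     ceiling(config$chimera_overlap_bp / 3) + 30L)
      host_cfg$protein_length_range$SSG <-
        c(min_len, max(min_len + 20L, config$protein_length_range$SSG[2]))
      host_cfg$exon_count_range$SSG <- c(1L, 1L)
      chim_hosts[[i]] <- design_gene(sprintf("gene_CHIM_%02d", i), "SSG",
                                     host_cfg)
    }
  }

  # -- layout: blocks left-to-right with random intergenic gaps
  # block kinds: "gene" (one design), "retro" (free insert),
  #              "chimera" (retro insert overlapping its host gene's CDS)
  blocks <- list()
  for (d in designs)
    blocks[[length(blocks) + 1L]] <- list(kind = "gene", design = d)
  idx <- 0L
  for (i in seq_len(config$n_retrogenes)) {
    idx <- idx + 1L
    blocks[[length(blocks) + 1L]] <-
      list(kind = "retro", parent = parents[idx], seq = retro_seqs[[idx]],
           retro_id = sprintf("retro_%02d", idx))
  }
  for (i in seq_len(config$n_chimeras)) {
    idx <- idx + 1L
    blocks[[length(blocks) + 1L]] <-
      list(kind = "chimera", parent = parents[idx], seq = retro_seqs[[idx]],
           retro_id = sprintf("retro_%02d", idx), host = chim_hosts[[i]])
  }
  if (length(blocks) > 1L) blocks <- blocks[sample(length(blocks))]

  block_len <- vapply(blocks, function(b) {
    switch(b$kind,
           gene = b$design$length,
           retro = nchar(b$seq),
           chimera = nchar(b$seq) + b$host$length - config$chimera_overlap_bp)
  }, numeric(1))
  min_gap <- 200L
  bg_total <- config$genome_size - sum(block_len)
  n_gaps <- length(blocks) + 1L
  if (bg_total < n_gaps * min_gap)
    stop("configuration error: genome_size too small for the planted features")
  # random composition of the background over the gaps
  w <- stats::runif(n_gaps)
  gap_len <- min_gap + floor((bg_total - n_gaps * min_gap) * w / sum(w))
  gap_len[n_gaps] <- bg_total - sum(gap_len[-n_gaps])

  genes_df <- list(); exons_df <- list(); retro_truth <- list()
  proteome <- character(0)
  seq_pieces <- character(0)
  pos <- 0L
  add_piece <- function(s) {
    seq_pieces[[length(seq_pieces) + 1L]] <<- s
    pos <<- pos + nchar(s)
  }
  chim_parent <- character(0)
  for (bi in seq_along(blocks)) {
    add_piece(random_dna(gap_len[bi]))
    b <- blocks[[bi]]
    if (b$kind == "gene" || b$kind == "chimera") {
      if (b$kind == "chimera") {
        # retro CDS first; the host gene begins `overlap` bp before its end
        retro_start <- pos + 1L
        add_piece(b$seq)
        retro_truth[[length(retro_truth) + 1L]] <-
          data.frame(retro_id = b$retro_id, chrom = chrom,
                     start = retro_start, end = pos, parent_id = b$parent,
                     chimeric_host = b$host$gene_id,
                     stringsAsFactors = FALSE)
        d <- b$host
        gstart <- pos - config$chimera_overlap_bp + 1L
        # host sequence minus the part already written by the retro tail
        add_piece(substr(d$seq, config$chimera_overlap_bp + 1L, d$length))
        chim_parent[d$gene_id] <- b$parent
      } else {
        d <- b$design
        gstart <- pos + 1L
        add_piece(d$seq)
      }
      genes_df[[length(genes_df) + 1L]] <-
        data.frame(gene_id = d$gene_id, chrom = chrom, strand = "+",
                   start = gstart, end = gstart + d$length - 1L,
                   exon_count = length(d$exon_start),
                   class = d$class, stringsAsFactors = FALSE)
      exons_df[[length(exons_df) + 1L]] <-
        data.frame(gene_id = d$gene_id,
                   start = gstart + d$exon_start - 1L,
                   end = gstart + d$exon_end - 1L,
                   stringsAsFactors = FALSE)
      proteome[d$gene_id] <- d$protein
    } else { # free retro insert
      retro_start <- pos + 1L
      add_piece(b$seq)
      retro_truth[[length(retro_truth) + 1L]] <-
        data.frame(retro_id = b$retro_id, chrom = chrom,
                   start = retro_start, end = pos, parent_id = b$parent,
                   chimeric_host = NA_character_, stringsAsFactors = FALSE)
    }
  }
  add_piece(random_dna(gap_len[n_gaps]))
  genome <- paste(seq_pieces, collapse = "")
  stopifnot(nchar(genome) == config$genome_size)

  genes <- if (length(genes_df)) do.call(rbind, genes_df) else
    data.frame(gene_id = character(0), chrom = character(0),
               strand = character(0), start = integer(0), end = integer(0),
               exon_count = integer(0), class = character(0))
  exons <- if (length(exons_df)) do.call(rbind, exons_df) else
    data.frame(gene_id = character(0), start = integer(0), end = integer(0))
  models <- gene_models(genes[, c("gene_id", "chrom", "strand", "start",
                                  "end", "exon_count")], exons)
  retro_df <- if (length(retro_truth)) do.call(rbind, retro_truth) else
    data.frame(retro_id = character(0), chrom = character(0),
               start = integer(0), end = integer(0),
               parent_id = character(0), chimeric_host = character(0))

  # -- origin flags and annotation tracks
  is_lsg <- genes$class %in% c("SSG", "GSG") &
    !grepl("^gene_CHIM", genes$gene_id)
  te_flag <- dup_flag <- rep(FALSE, nrow(genes))
  te_flag[is_lsg] <- stats::runif(sum(is_lsg)) < config$te_origin_frac
  dup_flag[is_lsg] <- stats::runif(sum(is_lsg)) < config$dup_origin_frac
  make_track <- function(cover_idx) {
    iv <- list()
    for (i in cover_idx) {
      m1 <- sample(10:50, 1L); m2 <- sample(10:50, 1L)
      iv[[length(iv) + 1L]] <- c(max(1L, genes$start[i] - m1),
                                 min(nchar(genome), genes$end[i] + m2))
    }
    iv
  }
  te_iv <- make_track(which(te_flag))
  dup_iv <- make_track(which(dup_flag))
  # random intergenic TE insertions (never fully containing a gene)
  n_rand_te <- round(config$te_density * config$genome_size / 10000)
  occupied <- IRanges::reduce(IRanges::IRanges(
    c(genes$start, retro_df$start), c(genes$end, retro_df$end)))
  tries <- 0L
  while (n_rand_te > 0 && tries < 50L * n_rand_te) {
    tries <- tries + 1L
    len <- sample(100:1000, 1L)
    st <- sample.int(max(1L, nchar(genome) - len), 1L)
    cand <- IRanges::IRanges(st, st + len - 1L)
    if (!length(IRanges::findOverlaps(cand, occupied))) {
      te_iv[[length(te_iv) + 1L]] <- c(st, st + len - 1L)
      n_rand_te <- n_rand_te - 1L
    }
  }
  as_track <- function(iv) {
    if (!length(iv))
      return(data.frame(chrom = character(0), start = integer(0),
                        end = integer(0)))
    m <- do.call(rbind, iv)
    o <- order(m[, 1])
    data.frame(chrom = chrom, start = m[o, 1], end = m[o, 2])
  }
  te_track <- as_track(te_iv)
  paralog_track <- as_track(dup_iv)

  # -- homolog panels
  clade_rate <- c(congeners = config$mutation_rates[["congener"]],
                  other_nematodes = config$mutation_rates[["other_nematode"]],
                  invertebrates = config$mutation_rates[["invertebrate"]],
                  vertebrates = config$mutation_rates[["vertebrate"]])
  shared_classes <- list(congeners = c("GSG", "EC"),
                         other_nematodes = "EC",
                         invertebrates = "EC",
                         vertebrates = "EC")
  panels <- list()
  for (clade in names(clade_rate)) {
    n_sp <- config$n_species_per_clade[[clade]]
    sp_list <- list()
    for (s in seq_len(n_sp)) {
      sp_id <- sprintf("%s_sp%d", sub("s$", "", clade), s)
      keep <- genes$class %in% shared_classes[[clade]] &
        !grepl("^gene_CHIM", genes$gene_id)
      ids <- genes$gene_id[keep]
      homs <- character(0)
      if (length(ids)) {
        homs <- vapply(proteome[ids], mutate_protein,
                       character(1), rate = clade_rate[[clade]])
        names(homs) <- paste0(sp_id, "|hom_", ids)
      }
      decoys <- character(config$decoys_per_species)
      for (dcy in seq_len(config$decoys_per_species))
        decoys[dcy] <- random_protein(sample(150:400, 1L))
      if (config$decoys_per_species > 0)
        names(decoys) <- sprintf("%s|decoy_%02d", sp_id,
                                 seq_len(config$decoys_per_species))
      sp_list[[sp_id]] <- c(homs, decoys)
    }
    panels[[clade]] <- sp_list
  }
  # UniProtKB stand-in: EC homologs at the deepest rate, decoys, and one
  # focal-species entry that panel loading must exclude by species tag
  og <- character(0)
  keep <- genes$class == "EC" & !grepl("^gene_CHIM", genes$gene_id)
  if (any(keep)) {
    og <- vapply(proteome[genes$gene_id[keep]], mutate_protein, character(1),
                 rate = clade_rate[["vertebrates"]])
    names(og) <- paste0("uniprot_sp|og_", genes$gene_id[keep])
  }
  if (config$decoys_per_species > 0) {
    od <- vapply(seq_len(config$decoys_per_species),
                 function(i) random_protein(sample(150:400, 1L)), character(1))
    names(od) <- sprintf("uniprot_sp|ogdecoy_%02d",
                         seq_len(config$decoys_per_species))
    og <- c(og, od)
  }
  panels[["outgroup_proteins"]] <- list(uniprot = og)
  # verbatim focal-species record written into the outgroup FASTA only:
  # panel loading must drop it by species tag, otherwise that SSG would
  # wrongly appear conserved
  ssg_ids <- genes$gene_id[genes$class == "SSG" &
                             !grepl("^gene_CHIM", genes$gene_id)]
  focal_leak <- if (length(ssg_ids))
    stats::setNames(unname(proteome[ssg_ids[1]]),
                    paste0("c_elegans|", ssg_ids[1]))
  else character(0)

  # -- expression: per-gene expressed flag at class prevalence
  expressed <- stats::runif(nrow(genes)) <
    config$expressed_prevalence[genes$class]

  # transcripts + mappings for expressed genes (clean, filter-passing), plus
  # planted decoys exercising each filter and the ambiguity rule
  tx <- character(0); map_rows <- list()
  for (i in which(expressed)) {
    gid <- genes$gene_id[i]
    tid <- paste0("tx_", gid)
    tx[tid] <- spliced_cds(genome, gid, models)
    mlen <- nchar(tx[tid])
    map_rows[[length(map_rows) + 1L]] <-
      data.frame(transcript_id = tid, chrom = chrom, strand = "+",
                 mapped_start = genes$start[i], mapped_end = genes$end[i],
                 mapped_length = mlen, identity_pct = 100,
                 coverage_in_mapping_pct = 100, coverage_whole_pct = 100,
                 score = mlen, stringsAsFactors = FALSE)
  }
  decoy_map <- function(tid, st, len, ident = 100, covm = 100, covw = 100,
                        score = len)
    data.frame(transcript_id = tid, chrom = chrom, strand = "+",
               mapped_start = st, mapped_end = st + len - 1L,
               mapped_length = len, identity_pct = ident,
               coverage_in_mapping_pct = covm, coverage_whole_pct = covw,
               score = score, stringsAsFactors = FALSE)
  if (nrow(genes) > 0) {
    # decoys sit in the leading intergenic gap, overlapping no gene
    dst <- max(1L, min(gap_len[1] - 160L, 10L))
    tx["tx_decoy_short"] <- random_dna(149L)
    map_rows[[length(map_rows) + 1L]] <- decoy_map("tx_decoy_short", dst, 149L)
    tx["tx_decoy_lowid"] <- random_dna(200L)
    map_rows[[length(map_rows) + 1L]] <-
      decoy_map("tx_decoy_lowid", dst, 150L, ident = 97.5)
    tx["tx_decoy_ambig"] <- random_dna(300L)
    map_rows[[length(map_rows) + 1L]] <- decoy_map("tx_decoy_ambig", dst, 300L,
                                                   score = 300)
    map_rows[[length(map_rows) + 1L]] <- decoy_map("tx_decoy_ambig", dst + 400L,
                                                   300L, score = 296)
  }
  mappings <- if (length(map_rows)) do.call(rbind, map_rows) else
    data.frame(transcript_id = character(0), chrom = character(0),
               strand = character(0), mapped_start = integer(0),
               mapped_end = integer(0), mapped_length = integer(0),
               identity_pct = numeric(0), coverage_in_mapping_pct = numeric(0),
               coverage_whole_pct = numeric(0), score = numeric(0))

  # -- read placements per stage; truth flag = at least one read planted
  stages <- names(config$stage_expression_profile)
  read_rows <- list(); expr_truth <- list()
  rl <- config$read_length
  for (stg in stages) {
    lam <- config$stage_expression_profile[[stg]]
    for (i in seq_len(nrow(genes))) {
      cnt <- if (expressed[i]) stats::rpois(1L, lam) else 0L
      if (cnt > 0) {
        span <- c(genes$start[i], genes$end[i])
        starts <- span[1] +
          sample.int(max(1L, span[2] - span[1] - rl + 2L), cnt,
                     replace = TRUE) - 1L
        read_rows[[length(read_rows) + 1L]] <-
          data.frame(read_id = sprintf("rd_%s_%s_%04d",
                                       gsub("[^A-Za-z0-9]", "", stg),
                                       genes$gene_id[i], seq_len(cnt)),
                     stage = stg, chrom = chrom, start = starts,
                     end = starts + rl - 1L, stringsAsFactors = FALSE)
      }
      expr_truth[[length(expr_truth) + 1L]] <-
        data.frame(gene_id = genes$gene_id[i], stage = stg,
                   expressed = cnt > 0, stringsAsFactors = FALSE)
    }
    # background intergenic reads pad the library size
    if (config$n_background_reads > 0 && gap_len[1] > rl + 20L) {
      starts <- sample.int(gap_len[1] - rl - 10L,
                           config$n_background_reads, replace = TRUE)
      read_rows[[length(read_rows) + 1L]] <-
        data.frame(read_id = sprintf("rd_%s_bg_%04d",
                                     gsub("[^A-Za-z0-9]", "", stg),
                                     seq_len(config$n_background_reads)),
                   stage = stg, chrom = chrom, start = starts,
                   end = starts + rl - 1L, stringsAsFactors = FALSE)
    }
  }
  reads <- if (length(read_rows)) do.call(rbind, read_rows) else
    data.frame(read_id = character(0), stage = character(0),
               chrom = character(0), start = integer(0), end = integer(0))
  expr_truth <- if (length(expr_truth)) do.call(rbind, expr_truth) else
    data.frame(gene_id = character(0), stage = character(0),
               expressed = logical(0))

  truth_genes <- data.frame(
    gene_id = genes$gene_id, class = genes$class,
    te_derived = te_flag, dup_derived = dup_flag,
    chimeric = grepl("^gene_CHIM", genes$gene_id),
    parent_id = ifelse(genes$gene_id %in% names(chim_parent),
                       chim_parent[genes$gene_id], NA_character_),
    expressed = expressed, stringsAsFactors = FALSE)

  world <- structure(list(
    config = config, genome = genome, chrom = chrom, models = models,
    proteome = proteome, panels = panels, outgroup_focal_leak = focal_leak,
    te_track = te_track, paralog_track = paralog_track,
    transcripts = tx, mappings = mappings, reads = reads,
    truth = list(genes = truth_genes, retro = retro_df,
                 expression = expr_truth)),
    class = "synthetic_world")
  if (!is.null(out_dir)) {
    write_world(world, out_dir)
    world$dir <- out_dir
  }
  world
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat("synthetic_world:", nchar(x$genome), "nt genome,",
      nrow(x$models$genes), "genes,", nrow(x$truth$retro), "retro loci\n")
  invisible(x)
}
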