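# Transcript-mapping filters, ambiguity resolution, EST-overlap expression
# calls, per-stage read counting with RPKM, and group comparisons.

#' Quality-filter transcript-to-genome mappings
#'
#' A mapping passes iff mapping length >= 150 bp, identity >= 98%, coverage
#' within the mapping >= 97%, and coverage of the whole transcript >= 75%
#' (all four thresholds inclusive).
#'
#' @param mappings data.frame as from [read_mapping_table()].
#' @param min_length,min_identity,min_cov_mapping,min_cov_whole The four
#'   thresholds (defaults 150, 98, 97, 75).
#' @return The passing subset.
#' @export
filter_mappings <- function(mappings, min_length = 150L, min_identity = 98,
                            min_cov_mapping = 97, min_cov_whole = 75) {
  mappings[mappings$mapped_length >= min_length &
             mappings$identity_pct >= min_identity &
             mappings$coverage_in_mapping_pct >= min_cov_mapping &
             mappings$coverage_whole_pct >= min_cov_whole, , drop = FALSE]
}

#' Resolve transcripts mapped to multiple loci
#'
#' For a transcript with several mappings, the whole transcript is discarded
#' as ambiguous when the runner-up score is within `rel_tol` of the best
#' (relative difference `(s1 - s2) / s1 < rel_tol`); otherwise only the best
#' mapping is retained. Single-locus transcripts are retained as-is.
#'
#' @param mappings data.frame of (already filtered) mappings.
#' @param rel_tol Relative score-difference threshold (default 0.02, i.e.
#'   2%; strict `<` discards).
#' @return data.frame with at most one row per transcript.
#' @export
resolve_ambiguous <- function(mappings, rel_tol = 0.02) {
  if (!nrow(mappings)) return(mappings)
  keep <- list()
  for (tid in unique(mappings$transcript_id)) {
    m <- mappings[mappings$transcript_id == tid, , drop = FALSE]
    if (nrow(m) == 1L) { keep[[tid]] <- m; next }
    o <- order(-m$score)
    s1 <- m$score[o[1]]; s2 <- m$score[o[2]]
    if ((s1 - s2) / s1 < rel_tol) next  # ambiguous: discard the transcript
    keep[[tid]] <- m[o[1], , drop = FALSE]
  }
  if (!length(keep)) return(mappings[0, , drop = FALSE])
  res <- do.call(rbind, keep)
  rownames(res) <- NULL
  res
}

#' EST-overlap expression call for a gene
#'
#' A gene counts as likely expressed iff its genomic span overlaps retained
#' transcript mappings by more than `min_overlap` bp in total (strict `>`).
#'
#' @param gene One row of a [gene_models()] genes table.
#' @param mappings Retained mappings ([resolve_ambiguous()] output).
#' @param min_overlap Overlap threshold in bp (default 100).
#' @return Logical.
#' @export
est_expressed <- function(gene, mappings, min_overlap = 100L) {
  m <- mappings[mappings$chrom == gene$chrom, , drop = FALSE]
  if (!nrow(m)) return(FALSE)
  span <- IRanges::IRanges(gene$start, gene$end)
  cov <- IRanges::intersect(span, IRanges::reduce(
    IRanges::IRanges(m$mapped_start, m$mapped_end)))
  sum(IRanges::width(cov)) > min_overlap
}

#' Reads per kilobase of gene length per million mapped reads
#'
#' rpkm = read_count / (gene_length / 1000) / (total_mapped_reads / 1e6)
#'      = read_count * 1e9 / (gene_length * total_mapped_reads).
#'
#' @param read_count Reads assigned to the gene.
#' @param gene_length_bp Gene length in bp (>= 1; genomic span by package
#'   convention).
#' @param total_mapped_reads Library size (>= 1).
#' @return RPKM value (>= 0).
#' @export
rpkm <- function(read_count, gene_length_bp, total_mapped_reads) {
  stopifnot(all(gene_length_bp >= 1), all(total_mapped_reads >= 1))
  read_count * 1e9 / (gene_length_bp * total_mapped_reads)
}

#' Per-gene per-stage read counts and RPKM
#'
#' A read counts for a gene when its interval overlaps the gene's genomic
#' span by at least 1 bp; a read overlapping several genes counts for each
#' (`multi = "all"`) or for none (`multi = "unique"`). The library size of a
#' stage is its total number of placed reads.
#'
#' @param models A [gene_models()] object.
#' @param reads data.frame of read placements (read_id, stage, chrom, start,
#'   end).
#' @param rpkm_threshold RPKM above which a gene counts as expressed
#'   (default 0, i.e. any nonzero signal; strict `>`).
#' @param multi Multi-gene read handling: `"all"` (default) or `"unique"`.
#' @return data.frame: gene_id, stage, read_count, rpkm, expressed.
#' @export
expression_matrix <- function(models, reads, rpkm_threshold = 0,
                              multi = c("all", "unique")) {
  multi <- match.arg(multi)
  genes <- models$genes
  gr_genes <- genes_granges(models)
  stages <- unique(reads$stage)
  rows <- list()
  for (stg in stages) {
    r <- reads[reads$stage == stg, , drop = FALSE]
    total <- nrow(r)
    gr_reads <- GenomicRanges::GRanges(r$chrom,
                                       IRanges::IRanges(r$start, r$end))
    hits <- GenomicRanges::findOverlaps(gr_reads, gr_genes,
                                        ignore.strand = TRUE)
    qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
    if (multi == "unique") {
      amb <- qh %in% qh[duplicated(qh)]
      qh <- qh[!amb]; sh <- sh[!amb]
    }
    cnt <- tabulate(sh, nbins = nrow(genes))
    rk <- if (total >= 1)
      rpkm(cnt, genes$end - genes$start + 1L, total) else rep(0, nrow(genes))
    rows[[length(rows) + 1L]] <- data.frame(
      gene_id = genes$gene_id, stage = stg, read_count = cnt, rpkm = rk,
      expressed = rk > rpkm_threshold, stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(gene_id = character(0), stage = character(0),
                      read_count = integer(0), rpkm = numeric(0),
                      expressed = logical(0)))
  do.call(rbind, rows)
}

#' Proportion of expressed genes per stage and group
#'
#' For each developmental stage and each label group, the fraction of the
#' group's genes with RPKM above the threshold.
#'
#' @param labels data.frame with gene_id and label.
#' @param expression data.frame from [expression_matrix()].
#' @param groups Label groups to report (default SSG and GSG).
#' @param rpkm_threshold Expression cutoff (default 0; strict `>`).
#' @return data.frame: stage, group, n_expressed, n_group, proportion.
#' @export
stage_proportions <- function(labels, expression,
                              groups = c("SSG", "GSG"),
                              rpkm_threshold = 0) {
  df <- merge(expression, labels[, c("gene_id", "label")], by = "gene_id")
  rows <- list()
  for (stg in unique(df$stage)) {
    for (g in groups) {
      sub <- df[df$stage == stg & df$label == g, , drop = FALSE]
      n_grp <- sum(labels$label == g)
      n_exp <- sum(sub$rpkm > rpkm_threshold)
      rows[[length(rows) + 1L]] <- data.frame(
        stage = stg, group = g, n_expressed = n_exp, n_group = n_grp,
        proportion = if (n_grp > 0) n_exp / n_grp else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Welch two-sample t-test
#'
#' Thin wrapper over [stats::t.test()] (two-sided, unequal variances).
#' Identical samples give t = 0, p = 1.
#'
#' @param a,b Numeric vectors.
#' @return List with `t` and `p`.
#' @export
two_sample_ttest <- function(a, b) {
  if (stats::var(c(a, b)) == 0) return(list(t = 0, p = 1))
  tt <- stats::t.test(a, b)
  list(t = unname(tt$statistic), p = unname(tt$p.value))
}
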