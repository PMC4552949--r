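#' Structural features of a gene
#'
#' Gene length is the genomic span of the gene (CDS span end - start + 1, in
#' nt, introns included); protein length is in aa; GC content is computed
#' over the gene's full genomic span, in percent (`gc_on = "span"`), or over
#' the spliced exonic sequence (`gc_on = "spliced"`).
#'
#' @param gene_id Gene identifier.
#' @param models A [gene_models()] object.
#' @param genome Named character vector of contig sequences (or a single
#'   unnamed contig).
#' @param protein Protein sequence of the gene (optional; protein length is
#'   NA without it).
#' @param gc_on `"span"` (default) or `"spliced"`.
#' @return A one-row data.frame: gene_id, gene_length_nt, protein_length_aa,
#'   exon_count, gc_content_pct.
#' @export
gene_features <- function(gene_id, models, genome, protein = NULL,
                          gc_on = c("span", "spliced")) {
  gc_on <- match.arg(gc_on)
  g <- models$genes[models$genes$gene_id == gene_id, , drop = FALSE]
  if (!nrow(g)) stop("unknown gene: ", gene_id)
  contig <- if (is.null(names(genome))) genome[[1]] else genome[[g$chrom]]
  if (is.null(contig) || is.na(contig)) stop("contig not in genome: ", g$chrom)
  ex <- models$exons[models$exons$gene_id == gene_id, , drop = FALSE]
  if (any(ex$start < 1) || any(ex$end > nchar(contig)))
    stop("exon outside contig bounds for gene ", gene_id)
  seq <- if (gc_on == "span") substr(contig, g$start, g$end)
  else paste(substring(contig, ex$start[order(ex$start)],
                       ex$end[order(ex$start)]), collapse = "")
  bases <- strsplit(toupper(seq), "")[[1]]
  gc <- 100 * sum(bases %in% c("G", "C")) / length(bases)
  data.frame(gene_id = gene_id,
             gene_length_nt = g$end - g$start + 1L,
             protein_length_aa = if (is.null(protein)) NA_integer_
             else nchar(protein),
             exon_count = nrow(ex),
             gc_content_pct = gc,
             stringsAsFactors = FALSE)
}

#' Feature table for a set of genes
#'
#' @inheritParams gene_features
#' @param proteome Named character vector of proteins (by gene id).
#' @return data.frame with one row per gene in `models`.
#' @export
feature_table <- function(models, genome, proteome = NULL,
                          gc_on = c("span", "spliced")) {
  gc_on <- match.arg(gc_on)
  do.call(rbind, lapply(models$genes$gene_id, function(gid)
    gene_features(gid, models, genome,
                  protein = if (!is.null(proteome)) proteome[[gid]],
                  gc_on = gc_on)))
}

#' One-way ANOVA across groups
#'
#' Classic fixed-effects one-way ANOVA (equal-variance pooling) via
#' [stats::oneway.test()]. When every observation is identical (zero
#' within-group variance with equal means) the statistic is defined as
#' F = 0, p = 1.
#'
#' @param groups List of >= 2 numeric vectors, each with >= 2 values.
#' @return List with `F` and `p`.
#' @export
one_way_anova <- function(groups) {
  if (length(groups) < 2L) stop("need >= 2 groups")
  if (any(lengths(groups) < 2L)) stop("each group needs >= 2 values")
  x <- unlist(groups)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  if (stats::var(x) == 0) return(list(F = 0, p = 1))
  ft <- stats::oneway.test(x ~ g, var.equal = TRUE)
  list(F = unname(ft$statistic), p = unname(ft$p.value))
}

#' Per-group feature summary with ANOVA
#'
#' Mean and standard error (sample SD / sqrt(n), n-1 denominator) of each
#' structural metric per LSG class, plus transcript-support percentage and a
#' one-way ANOVA F/p per metric across the groups.
#'
#' @param features A [feature_table()] data.frame.
#' @param labels data.frame with gene_id and label columns (from
#'   [classify_proteome()]).
#' @param transcript_support Optional named logical (by gene id): EST
#'   transcript support per gene.
#' @return List with `stats` (one row per group x metric: group, metric, n,
#'   mean, se), `transcript_pct` (named numeric per group) and `anova`
#'   (one row per metric: metric, F, p).
#' @export
group_feature_stats <- function(features, labels,
                                transcript_support = NULL) {
  df <- merge(features, labels[, c("gene_id", "label")], by = "gene_id")
  metrics <- c("gene_length_nt", "protein_length_aa", "exon_count",
               "gc_content_pct")
  groups <- c("SSG", "GSG", "EC")
  rows <- list(); anova_rows <- list()
  for (m in metrics) {
    by_grp <- lapply(groups, function(g) df[[m]][df$label == g])
    names(by_grp) <- groups
    for (g in groups) {
      v <- by_grp[[g]]
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, metric = m, n = length(v),
        mean = if (length(v)) mean(v) else NA_real_,
        se = if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else NA_real_,
        stringsAsFactors = FALSE)
    }
    usable <- Filter(function(v) length(v) >= 2, by_grp)
    anova_rows[[length(anova_rows) + 1L]] <- data.frame(
      metric = m,
      F = if (length(usable) >= 2) one_way_anova(usable)$F else NA_real_,
      p = if (length(usable) >= 2) one_way_anova(usable)$p else NA_real_,
      stringsAsFactors = FALSE)
  }
  tp <- NULL
  if (!is.null(transcript_support)) {
    tp <- vapply(groups, function(g) {
      ids <- df$gene_id[df$label == g]
      if (!length(ids)) return(NA_real_)
      100 * mean(transcript_support[ids])
    }, numeric(1))
  }
  list(stats = do.call(rbind, rows),
       transcript_pct = tp,
       anova = do.call(rbind, anova_rows))
}
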