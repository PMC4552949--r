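#' Hierarchical lineage-specificity classification
#'
#' A focal-species protein is screened against ordered clade panels. Panels
#' outside the genus (other nematodes, invertebrates, vertebrates, and the
#' outgroup protein set) decide conservation; the congener panel decides
#' genus specificity:
#' * hit in at least one non-genus panel -> **EC** (evolutionarily conserved)
#' * hits only within congener panels     -> **GSG** (genus-specific)
#' * no hit in any panel                  -> **SSG** (species-specific)
#'
#' The outcome depends only on which panels contain hits, so screening order
#' cannot change a label; panels are nonetheless searched non-genus-first
#' with short-circuiting when only the label is needed.
#'
#' @param query Amino-acid sequence of the protein.
#' @param panels Named list of panels; each panel is a list of per-species
#'   named character vectors of protein sequences. Must contain a
#'   `congeners` panel; every other panel is treated as non-genus.
#' @param cutoff E-value threshold for a hit (default 1e-5).
#' @param collect_evalues If TRUE, also return the best E-value per panel
#'   (disables short-circuiting).
#' @return The label (`"SSG"`, `"GSG"` or `"EC"`), or, with
#'   `collect_evalues`, a list with `label` and `best_evalue` (named numeric).
#' @export
classify_gene <- function(query, panels, cutoff = 1e-5,
                          collect_evalues = FALSE) {
  if (!length(panels)) stop("configuration error: empty panel set")
  if (!"congeners" %in% names(panels))
    stop("configuration error: panels must include a 'congeners' panel")
  non_genus <- setdiff(names(panels), "congeners")
  scheme <- scoring_scheme(select_matrix(nchar(query)))
  panel_e <- function(panel) {
    seqs <- unlist(unname(lapply(panel, as.character)))
    panel_best_evalue(query, seqs, scheme = scheme)
  }
  if (!collect_evalues) {
    for (p in non_genus)
      if (panel_e(panels[[p]]) <= cutoff) return("EC")
    if (panel_e(panels[["congeners"]]) <= cutoff) return("GSG")
    return("SSG")
  }
  best <- vapply(panels, panel_e, numeric(1))
  label <- if (any(best[non_genus] <= cutoff)) "EC"
  else if (best[["congeners"]] <= cutoff) "GSG"
  else "SSG"
  list(label = label, best_evalue = best)
}

#' Classify a whole proteome into SSG / GSG / EC
#'
#' Applies [classify_gene()] to every protein. When several isoforms share a
#' gene (via `gene_of`), the gene is EC if any isoform has a non-genus hit,
#' GSG if any isoform has a congener hit and none has a non-genus hit, and
#' SSG only if all isoforms are hit-free — the most conservative collapse
#' for specificity.
#'
#' @param proteome Named character vector of protein sequences.
#' @param panels As in [classify_gene()].
#' @param cutoff E-value threshold (default 1e-5).
#' @param gene_of Optional named character vector mapping protein id ->
#'   gene id (default: each protein is its own gene).
#' @return A list with `labels` (data.frame gene_id, label, and one
#'   `evalue_<panel>` column per panel holding the best E-value over
#'   isoforms) and `counts` (named integer: SSG, GSG, EC).
#' @export
classify_proteome <- function(proteome, panels, cutoff = 1e-5,
                              gene_of = NULL) {
  ids <- names(proteome)
  if (anyDuplicated(ids)) stop("duplicate protein ids in proteome")
  if (is.null(gene_of)) gene_of <- stats::setNames(ids, ids)
  res <- lapply(as.character(proteome), classify_gene, panels = panels,
                cutoff = cutoff, collect_evalues = TRUE)
  emat <- do.call(rbind, lapply(res, `[[`, "best_evalue"))
  per_prot <- data.frame(gene_id = unname(gene_of[ids]),
                         stringsAsFactors = FALSE)
  per_prot <- cbind(per_prot, as.data.frame(emat))
  # collapse isoforms: min E-value per panel within a gene
  agg <- stats::aggregate(per_prot[, -1, drop = FALSE],
                          by = list(gene_id = per_prot$gene_id), FUN = min)
  non_genus <- setdiff(names(panels), "congeners")
  label <- ifelse(
    apply(agg[, non_genus, drop = FALSE] <= cutoff, 1, any), "EC",
    ifelse(agg[["congeners"]] <= cutoff, "GSG", "SSG"))
  labels <- data.frame(gene_id = agg$gene_id, label = label,
                       stringsAsFactors = FALSE)
  names(agg)[-1] <- paste0("evalue_", names(agg)[-1])
  labels <- cbind(labels, agg[, -1, drop = FALSE])
  counts <- stats::setNames(
    vapply(c("SSG", "GSG", "EC"), function(l) sum(label == l), integer(1)),
    c("SSG", "GSG", "EC"))
  stopifnot(sum(counts) == nrow(labels))
  list(labels = labels, counts = counts)
}
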