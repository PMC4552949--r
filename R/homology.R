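#' Scoring schemes for length-stratified protein homology search
#'
#' Short proteins carry less alignment information, so the screening pipeline
#' scores them with shallower matrices: PAM30 for queries under 30 aa, PAM70
#' for 30-70 aa (both boundaries inclusive), and BLOSUM62 above 70 aa. Each
#' scheme bundles the substitution matrix, affine gap penalties (BLAST
#' conventions: a gap of length k costs `gap_open + k * gap_extend`), and the
#' Karlin-Altschul parameters lambda and K used to convert raw scores into
#' E-values, E = K * m * n * exp(-lambda * S).
#'
#' `'X'` scores 0 against every residue; `'*'` (stop, arising only in
#' translated genomic frames) scores -30 against everything so that local
#' alignments never cross a stop codon.
#'
#' @param matrix_name One of `"BLOSUM62"`, `"PAM70"`, `"PAM30"`.
#' @param gap_open,gap_extend Positive penalties; defaults are the BLAST
#'   defaults for each matrix (11/1, 10/1, 9/1).
#' @param lambda,K Karlin-Altschul parameters; defaults are the NCBI gapped
#'   values for the matrix/gap combination.
#' @return An object of class `scoring_scheme`.
#' @export
scoring_scheme <- function(matrix_name = c("BLOSUM62", "PAM70", "PAM30"),
                           gap_open = NULL, gap_extend = NULL,
                           lambda = NULL, K = NULL) {
  matrix_name <- match.arg(matrix_name)
  defaults <- list(
    BLOSUM62 = list(gap_open = 11, gap_extend = 1, lambda = 0.267, K = 0.041),
    PAM70    = list(gap_open = 10, gap_extend = 1, lambda = 0.291, K = 0.089),
    PAM30    = list(gap_open = 9,  gap_extend = 1, lambda = 0.294, K = 0.110)
  )[[matrix_name]]
  if (is.null(gap_open)) gap_open <- defaults$gap_open
  if (is.null(gap_extend)) gap_extend <- defaults$gap_extend
  if (is.null(lambda)) lambda <- defaults$lambda
  if (is.null(K)) K <- defaults$K
  stopifnot(gap_open >= 0, gap_extend >= 0, lambda > 0, K > 0)
  mat <- .load_scoring_matrix(matrix_name)
  structure(
    list(matrix_name = matrix_name, matrix = mat,
         gap_open = gap_open, gap_extend = gap_extend,
         lambda = lambda, K = K),
    class = "scoring_scheme"
  )
}

# Biostrings ships the published matrices; adjust the ambiguity letters:
# X scores 0 everywhere, * scores -30 so alignments never span stop codons.
.matrix_cache <- new.env(parent = emptyenv())
.load_scoring_matrix <- function(matrix_name) {
  if (!is.null(.matrix_cache[[matrix_name]])) return(.matrix_cache[[matrix_name]])
  env <- new.env()
  utils::data(list = matrix_name, package = "Biostrings", envir = env)
  mat <- env[[matrix_name]]
  mat["X", ] <- 0L
  mat[, "X"] <- 0L
  mat["*", ] <- -30L
  mat[, "*"] <- -30L
  .matrix_cache[[matrix_name]] <- mat
  mat
}

#' Select the scoring matrix for a query by protein length
#'
#' @param query_length_aa Query length in amino acids (>= 1).
#' @param bounds Length-class boundaries `c(lower, upper)`; queries shorter
#'   than `lower` use PAM30, queries in `[lower, upper]` use PAM70 (both
#'   boundaries inclusive to the middle class), longer queries use BLOSUM62.
#' @return The matrix name as a string.
#' @export
select_matrix <- function(query_length_aa, bounds = c(30L, 70L)) {
  if (!is.numeric(query_length_aa) || length(query_length_aa) != 1L ||
      is.na(query_length_aa) || query_length_aa < 1)
    stop("query_length_aa must be a positive integer")
  if (query_length_aa < bounds[1]) "PAM30"
  else if (query_length_aa <= bounds[2]) "PAM70"
  else "BLOSUM62"
}

.AA_STANDARD <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]

.check_protein <- function(seq, allow_stop = FALSE) {
  letters_ok <- c(.AA_STANDARD, "X", if (allow_stop) "*")
  bad <- setdiff(unique(strsplit(seq, "")[[1]]), letters_ok)
  if (length(bad))
    stop("invalid amino-acid characters: ", paste(bad, collapse = ", "))
  invisible(TRUE)
}

#' Optimal local protein alignment under affine gaps
#'
#' Full Smith-Waterman dynamic programming (no heuristic seeding), delegated
#' to [Biostrings::pairwiseAlignment()] with `type = "local"`. Returns `NULL`
#' when no positive-scoring local alignment exists.
#'
#' @param query,target Amino-acid strings (20-letter alphabet plus `'X'`).
#' @param scheme A [scoring_scheme()].
#' @return A one-row data.frame (class `alignment_hit`) with raw score, bit
#'   score, identity fraction over aligned columns, and half-open query and
#'   target ranges, or `NULL` if the optimum is <= 0.
#' @export
smith_waterman <- function(query, target, scheme = scoring_scheme("BLOSUM62")) {
  stopifnot(nzchar(query), nzchar(target))
  .check_protein(query); .check_protein(target, allow_stop = TRUE)
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(query), Biostrings::AAString(target),
    type = "local", substitutionMatrix = scheme$matrix,
    gapOpening = scheme$gap_open, gapExtension = scheme$gap_extend)
  s <- Biostrings::score(pa)
  if (s <= 0) return(NULL)
  p <- Biostrings::pattern(pa); t <- Biostrings::subject(pa)
  data.frame(
    raw_score = s,
    bit_score = (scheme$lambda * s - log(scheme$K)) / log(2),
    identity_frac = Biostrings::pid(pa, type = "PID1") / 100,
    query_start = Biostrings::start(p) - 1L, query_end = Biostrings::end(p),
    target_start = Biostrings::start(t) - 1L, target_end = Biostrings::end(t),
    matrix_name = scheme$matrix_name,
    stringsAsFactors = FALSE
  )
}

#' Karlin-Altschul E-value of a raw alignment score
#'
#' E = K * m * n * exp(-lambda * S): the expected number of chance local
#' alignments scoring at least S between a length-m query and a search space
#' of n residues. Strictly decreasing in S, linear in m and n.
#'
#' @param raw_score Raw alignment score S.
#' @param m Query length (aa), >= 1.
#' @param n Total target search-space length (aa), >= 1; for a panel this is
#'   the concatenated residue count of all panel sequences (database-style).
#' @param scheme A [scoring_scheme()] supplying lambda and K.
#' @return The E-value (>= 0).
#' @export
evalue <- function(raw_score, m, n, scheme = scoring_scheme("BLOSUM62")) {
  stopifnot(m >= 1, n >= 1)
  scheme$K * m * n * exp(-scheme$lambda * raw_score)
}

# Best raw local-alignment score of one query against each sequence of a set.
# One vectorized pairwiseAlignment call; local scores are symmetric under
# exchange of pattern and subject, so the panel set is passed as patterns.
.panel_scores <- function(query, panel_seqs, scheme) {
  if (length(panel_seqs) == 0L) return(numeric(0))
  Biostrings::score(Biostrings::pairwiseAlignment(
    Biostrings::AAStringSet(panel_seqs), Biostrings::AAString(query),
    type = "local", substitutionMatrix = scheme$matrix,
    gapOpening = scheme$gap_open, gapExtension = scheme$gap_extend))
}

#' Best E-value of a query against a panel of proteins
#'
#' The search space n is the total concatenated length of the panel
#' (database-style E-value composition, matching BLAST semantics).
#'
#' @param query Amino-acid string.
#' @param panel_seqs Character vector (or `AAStringSet`) of panel proteins.
#' @param scheme A [scoring_scheme()]; defaults to the matrix selected by
#'   query length via [select_matrix()].
#' @return Best (smallest) E-value, or `Inf` for an empty panel.
#' @export
panel_best_evalue <- function(query, panel_seqs, scheme = NULL) {
  panel_seqs <- as.character(panel_seqs)
  if (length(panel_seqs) == 0L) return(Inf)
  if (is.null(scheme)) scheme <- scoring_scheme(select_matrix(nchar(query)))
  scores <- .panel_scores(query, panel_seqs, scheme)
  n_total <- sum(nchar(panel_seqs))
  min(evalue(max(scores), m = nchar(query), n = n_total, scheme = scheme))
}

#' Does a query protein have a homology hit in a panel?
#'
#' TRUE iff some panel sequence yields an E-value at or below `cutoff`, using
#' the scoring matrix selected by the query's length. An empty panel never
#' hits.
#'
#' @inheritParams panel_best_evalue
#' @param cutoff E-value threshold (default 1e-5, the screening cutoff).
#' @return Logical.
#' @export
has_hit <- function(query, panel_seqs, cutoff = 1e-5, scheme = NULL) {
  panel_best_evalue(query, panel_seqs, scheme) <= cutoff
}

#' Read a precomputed tabular hit table
#'
#' Accepts a BLAST "outfmt 6"-compatible subset (tab-separated: query_id,
#' target_id, identity_pct, align_len, e_value, bit_score) so that real
#' BLAST output can substitute for the internal aligner.
#'
#' @param path Path to the TSV file (no header).
#' @return A data.frame with the six named columns.
#' @export
read_hit_table <- function(path) {
  tab <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 6) stop("hit table needs >= 6 columns: ", path)
  tab <- tab[, 1:6]
  names(tab) <- c("query_id", "target_id", "identity_pct", "align_len",
                  "e_value", "bit_score")
  tab
}
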