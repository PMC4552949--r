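# Independent oracles used across tests. These deliberately share no code
# with the package internals.

# Exhaustive enumeration of local alignments under affine gaps: the best
# local alignment starts and ends on a substitution column; from each start
# cell every operation sequence is enumerated recursively (no memoization).
# Gap of length k costs open + k * ext. Feasible for sequences up to ~7 aa.
enum_local_score <- function(a, b, mat, open, ext) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  extend <- function(i, j, last) {
    best <- 0  # stopping is always allowed
    if (i <= n && j <= m) {
      best <- max(best, mat[av[i], bv[j]] + extend(i + 1, j + 1, "M"))
    }
    if (i <= n) {
      cost <- if (last == "X") ext else open + ext
      best <- max(best, -cost + extend(i + 1, j, "X"))
    }
    if (j <= m) {
      cost <- if (last == "Y") ext else open + ext
      best <- max(best, -cost + extend(i, j + 1, "Y"))
    }
    best
  }
  best <- 0
  for (i in seq_len(n))
    for (j in seq_len(m))
      best <- max(best, mat[av[i], bv[j]] + extend(i + 1, j + 1, "M"))
  best
}

# Naive re-computation of gene features straight from the sequences,
# independent of the package's interval containers.
naive_gene_features <- function(contig, exon_starts, exon_ends) {
  span <- substr(contig, min(exon_starts), max(exon_ends))
  ch <- strsplit(span, "")[[1]]
  list(gene_length = nchar(span),
       exon_count = length(exon_starts),
       gc_pct = 100 * sum(ch == "G" | ch == "C") / length(ch))
}

# Minimal genomic-match row for merge tests.
.acc_match <- function(start, end)
  data.frame(protein_id = "p", chrom = "c", strand = "+", frame = 0L,
             start = start, end = end, aa_identity_frac = 0.9,
             matched_aa_length = (end - start + 1) %/% 3, score = 100,
             stringsAsFactors = FALSE)

# Union length of 1-based inclusive intervals by position marking.
naive_union_overlap <- function(span, ivs) {
  covered <- rep(FALSE, span[2] - span[1] + 1)
  for (iv in ivs) {
    lo <- max(iv[1], span[1]); hi <- min(iv[2], span[2])
    if (lo <= hi) covered[(lo - span[1] + 1):(hi - span[1] + 1)] <- TRUE
  }
  sum(covered)
}
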