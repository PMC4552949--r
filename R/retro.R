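# Retrogene and chimeric-gene screen: six-frame translated matching of the
# proteome onto the genome, adjacent-match merging, parental assignment,
# intron-aware spliced verification, and CDS-overlap chimera calling.

#' Six-frame translations of a genome
#'
#' Precomputes the amino-acid translation of every contig in all six frames
#' (stop codons as `'*'`), so repeated translated searches do not re-translate.
#'
#' @param genome Named character vector of contig sequences.
#' @return A list (class `genome_frames`) keyed by contig, each element a
#'   list of 6 entries with `aa`, `strand` (+/-), `frame` (0-2) and
#'   `contig_len`.
#' @export
genome_frames <- function(genome) {
  if (is.null(names(genome))) names(genome) <- paste0("contig", seq_along(genome))
  out <- list()
  for (chrom in names(genome)) {
    d <- Biostrings::DNAString(genome[[chrom]])
    L <- length(d)
    rc <- Biostrings::reverseComplement(d)
    fr <- list()
    for (strand in c("+", "-")) {
      src <- if (strand == "+") d else rc
      for (f in 0:2) {
        n_nt <- L - f
        n_nt <- n_nt - n_nt %% 3L
        aa <- if (n_nt >= 3L)
          as.character(suppressWarnings(
            Biostrings::translate(Biostrings::subseq(src, f + 1L, f + n_nt),
                                  if.fuzzy.codon = "X")))
        else ""
        fr[[length(fr) + 1L]] <- list(aa = aa, strand = strand, frame = f,
                                      contig_len = L)
      }
    }
    out[[chrom]] <- fr
  }
  structure(out, class = "genome_frames")
}

# frame aa positions (1-based, inclusive) -> genomic nt interval (1-based
# inclusive, forward-strand coordinates)
.aa_to_genomic <- function(aa_start, aa_end, frame, strand, contig_len) {
  nt1 <- frame + 3L * (aa_start - 1L) + 1L
  nt2 <- frame + 3L * aa_end
  if (strand == "+") c(nt1, nt2)
  else c(contig_len - nt2 + 1L, contig_len - nt1 + 1L)
}

#' Translated protein-to-genome matching
#'
#' Finds local alignments of a protein against all six translated frames of
#' the genome, retaining matches with E-value at or below `evalue_cutoff`
#' (the search space n is the total residue count over all frames). Within a
#' frame, matches are found iteratively: each hit is masked with stop
#' characters and the frame realigned, up to `max_hits_per_frame` hits.
#' Internal stop codons score -30, so no match crosses one.
#'
#' @param protein_id,protein Identifier and amino-acid sequence of the query.
#' @param genome Named character vector of contigs, or a precomputed
#'   [genome_frames()] object.
#' @param evalue_cutoff E-value threshold (default 1e-3).
#' @param scheme A [scoring_scheme()] (default BLOSUM62).
#' @param max_hits_per_frame Maximum matches recovered per frame (default 4).
#' @return data.frame of genomic matches: protein_id, chrom, strand, frame,
#'   start, end (1-based inclusive nt), aa_identity_frac, matched_aa_length,
#'   score.
#' @export
translated_match <- function(protein_id, protein, genome,
                             evalue_cutoff = 1e-3,
                             scheme = scoring_scheme("BLOSUM62"),
                             max_hits_per_frame = 4L) {
  frames <- if (inherits(genome, "genome_frames")) genome
  else genome_frames(genome)
  n_total <- sum(vapply(frames, function(fr)
    sum(vapply(fr, function(x) nchar(x$aa), numeric(1))), numeric(1)))
  if (n_total < 1) return(.empty_matches())
  rows <- list()
  for (chrom in names(frames)) {
    for (fr in frames[[chrom]]) {
      if (!nzchar(fr$aa)) next
      subj <- fr$aa
      for (it in seq_len(max_hits_per_frame)) {
        pa <- Biostrings::pairwiseAlignment(
          Biostrings::AAString(protein), Biostrings::AAString(subj),
          type = "local", substitutionMatrix = scheme$matrix,
          gapOpening = scheme$gap_open, gapExtension = scheme$gap_extend)
        s <- Biostrings::score(pa)
        if (s <= 0 ||
            evalue(s, nchar(protein), n_total, scheme) > evalue_cutoff)
          break
        sb <- Biostrings::subject(pa)
        a1 <- Biostrings::start(sb); a2 <- Biostrings::end(sb)
        g <- .aa_to_genomic(a1, a2, fr$frame, fr$strand, fr$contig_len)
        pat <- Biostrings::pattern(pa)
        rows[[length(rows) + 1L]] <- data.frame(
          protein_id = protein_id, chrom = chrom, strand = fr$strand,
          frame = fr$frame, start = g[1], end = g[2],
          aa_identity_frac = Biostrings::pid(pa, type = "PID1") / 100,
          matched_aa_length = Biostrings::end(pat) -
            Biostrings::start(pat) + 1L,
          score = s, stringsAsFactors = FALSE)
        # mask the hit and look for the next one in this frame
        substr(subj, a1, a2) <- strrep("*", a2 - a1 + 1L)
      }
    }
  }
  if (!length(rows)) return(.empty_matches())
  do.call(rbind, rows)
}

.empty_matches <- function() {
  data.frame(protein_id = character(0), chrom = character(0),
             strand = character(0), frame = integer(0), start = integer(0),
             end = integer(0), aa_identity_frac = numeric(0),
             matched_aa_length = integer(0), score = numeric(0))
}

#' Merge adjacent genomic matches
#'
#' Within one protein/chromosome/strand, two matches merge when the genomic
#' gap between them (nt between the end of one and the start of the next) is
#' strictly less than `max_gap`; overlapping matches merge unconditionally;
#' chaining is transitive. Merged identity is the alignment-length-weighted
#' mean; matched lengths and scores are summed; the frame of the longest
#' member is retained.
#'
#' @param matches data.frame as returned by [translated_match()] (one
#'   protein; may span chromosomes/strands, which are merged separately).
#' @param max_gap Merge threshold in nt (default 40; strict `<`).
#' @return data.frame of merged matches with the same columns.
#' @export
merge_adjacent <- function(matches, max_gap = 40L) {
  if (!nrow(matches)) return(matches)
  out <- list()
  for (key in unique(paste(matches$protein_id, matches$chrom,
                           matches$strand))) {
    m <- matches[paste(matches$protein_id, matches$chrom,
                       matches$strand) == key, , drop = FALSE]
    m <- m[order(m$start, m$end), , drop = FALSE]
    cur <- m[1, , drop = FALSE]
    flush <- function(cur) out[[length(out) + 1L]] <<- cur
    i <- 2L
    while (i <= nrow(m)) {
      gap <- m$start[i] - cur$end - 1L
      if (gap < max_gap) {
        w <- c(cur$matched_aa_length, m$matched_aa_length[i])
        cur$aa_identity_frac <-
          sum(w * c(cur$aa_identity_frac, m$aa_identity_frac[i])) / sum(w)
        if (m$matched_aa_length[i] > cur$matched_aa_length)
          cur$frame <- m$frame[i]
        cur$matched_aa_length <- sum(w)
        cur$score <- cur$score + m$score[i]
        cur$end <- max(cur$end, m$end[i])
      } else {
        flush(cur)
        cur <- m[i, , drop = FALSE]
      }
      i <- i + 1L
    }
    flush(cur)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Keep merged matches with sufficient identity and length
#'
#' A merged match survives iff its amino-acid identity exceeds 30% and its
#' matched length exceeds 50 aa (both strict).
#'
#' @param merged data.frame of merged matches.
#' @param min_identity Identity threshold (default 0.30, strict `>`).
#' @param min_aa_length Length threshold in aa (default 50, strict `>`).
#' @return The passing subset.
#' @export
filter_merged <- function(merged, min_identity = 0.30, min_aa_length = 50L) {
  merged[merged$aa_identity_frac > min_identity &
           merged$matched_aa_length > min_aa_length, , drop = FALSE]
}

# translate a merged locus in its recorded frame/strand
.locus_translation <- function(locus, genome) {
  contig <- genome[[locus$chrom]]
  seq <- substr(contig, locus$start, locus$end)
  d <- Biostrings::DNAString(seq)
  if (locus$strand == "-") d <- Biostrings::reverseComplement(d)
  n <- length(d) - length(d) %% 3L
  if (n < 3L) return("")
  as.character(suppressWarnings(
    Biostrings::translate(Biostrings::subseq(d, 1L, n),
                          if.fuzzy.codon = "X")))
}

#' Assign the closest multi-exon parent to a candidate retro locus
#'
#' The translated merged locus is aligned against every candidate parent
#' protein (genes with >= 3 exons, i.e. >= 2 introns); the highest-similarity
#' parent passing the alignment is returned. Ties break deterministically:
#' highest similarity, then longest parent, then lexicographic id.
#'
#' @param locus One merged-match row.
#' @param genome Named character vector of contigs.
#' @param parent_proteins Named character vector of multi-exon candidate
#'   parent proteins.
#' @param min_identity Minimum identity over aligned columns (default 0.30).
#' @param scheme A [scoring_scheme()].
#' @return List with `parent_id` and `similarity`, or `NULL` when no parent
#'   passes.
#' @export
assign_parent <- function(locus, genome, parent_proteins,
                          min_identity = 0.30,
                          scheme = scoring_scheme("BLOSUM62")) {
  if (!length(parent_proteins)) return(NULL)
  aa <- .locus_translation(locus, genome)
  if (!nzchar(aa)) return(NULL)
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAStringSet(parent_proteins), Biostrings::AAString(aa),
    type = "local", substitutionMatrix = scheme$matrix,
    gapOpening = scheme$gap_open, gapExtension = scheme$gap_extend)
  sc <- Biostrings::score(pa)
  sim <- Biostrings::pid(pa, type = "PID1") / 100
  ok <- sc > 0 & sim > min_identity
  if (!any(ok)) return(NULL)
  ord <- order(-sim, -nchar(parent_proteins),
               names(parent_proteins))
  ord <- ord[ok[ord]]
  best <- ord[1]
  list(parent_id = names(parent_proteins)[best], similarity = sim[best])
}

#' Intron-aware verification of a candidate retrogene locus
#'
#' An internal spliced-alignment scorer standing in for a protein-to-genome
#' aligner with intron modelling: the parent protein is cut into its per-exon
#' peptide blocks and each block is locally aligned against the six frames of
#' the locus extended by `flank_bp` on both sides. The reported score is the
#' sum of the aligned block scores minus `intron_penalty` for every genomic
#' gap larger than `min_intron` nt between consecutive aligned blocks — an
#' intronless retrocopy keeps its blocks contiguous and pays no penalty,
#' while a spliced (intron-bearing) locus does. Also reports how many parent
#' introns fall inside the matched part of the parent, and the fraction of
#' the parent covered.
#'
#' @param retro_locus List/row with chrom, start, end (1-based inclusive).
#' @param genome Named character vector of contigs.
#' @param parent_id Parent gene id within `models`.
#' @param models A [gene_models()] object (codon-aligned exon boundaries).
#' @param parent_protein Parent protein sequence.
#' @param flank_bp Flanking region on each side (default 10000, clipped at
#'   contig ends).
#' @param min_intron Minimum genomic gap counted as an intron (default 30 nt).
#' @param intron_penalty Score penalty per detected intron (default 10).
#' @param block_min_score Minimum raw score for a block to count as aligned
#'   (default 25).
#' @param scheme A [scoring_scheme()].
#' @param mask Optional data.frame of genomic intervals (start, end; same
#'   contig) to mask with `N` inside the window — used to hide the parent's
#'   own annotated locus so the copy, not the source, is what verifies.
#' @return List with `spliced_align_score`, `introns_in_match` and
#'   `coverage` (fraction of parent residues aligned).
#' @export
verify_intronless <- function(retro_locus, genome, parent_id, models,
                              parent_protein, flank_bp = 10000L,
                              min_intron = 30L, intron_penalty = 10,
                              block_min_score = 25,
                              scheme = scoring_scheme("BLOSUM62"),
                              mask = NULL) {
  contig <- genome[[retro_locus$chrom]]
  ws <- max(1L, retro_locus$start - flank_bp)
  we <- min(nchar(contig), retro_locus$end + flank_bp)
  window <- substr(contig, ws, we)
  if (!is.null(mask) && nrow(mask)) {
    for (i in seq_len(nrow(mask))) {
      a <- max(mask$start[i], ws); b <- min(mask$end[i], we)
      if (a <= b)
        substr(window, a - ws + 1L, b - ws + 1L) <-
          strrep("N", b - a + 1L)
    }
  }
  window <- stats::setNames(window, retro_locus$chrom)
  frames <- genome_frames(window)[[1]]

  ex <- models$exons[models$exons$gene_id == parent_id, , drop = FALSE]
  ex <- ex[order(ex$start), , drop = FALSE]
  aa_len <- (ex$end - ex$start + 1L) %/% 3L
  aa_end <- cumsum(aa_len)
  aa_start <- aa_end - aa_len + 1L
  k <- nrow(ex)

  block_score <- numeric(k); block_aligned <- logical(k)
  block_pat <- vector("list", k); block_gpos <- vector("list", k)
  for (j in seq_len(k)) {
    pep <- substr(parent_protein, aa_start[j], aa_end[j])
    if (nchar(pep) < 5L) next
    best <- NULL
    for (fr in frames) {
      if (!nzchar(fr$aa)) next
      pa <- Biostrings::pairwiseAlignment(
        Biostrings::AAString(pep), Biostrings::AAString(fr$aa),
        type = "local", substitutionMatrix = scheme$matrix,
        gapOpening = scheme$gap_open, gapExtension = scheme$gap_extend)
      s <- Biostrings::score(pa)
      if (is.null(best) || s > best$s) {
        sb <- Biostrings::subject(pa)
        g <- .aa_to_genomic(Biostrings::start(sb), Biostrings::end(sb),
                            fr$frame, fr$strand, fr$contig_len)
        best <- list(s = s,
                     pat = c(Biostrings::start(Biostrings::pattern(pa)),
                             Biostrings::end(Biostrings::pattern(pa))),
                     g = g + ws - 1L)
      }
    }
    if (!is.null(best) && best$s >= block_min_score) {
      block_aligned[j] <- TRUE
      block_score[j] <- best$s
      block_pat[[j]] <- best$pat
      block_gpos[[j]] <- best$g
    }
  }
  aligned_aa <- sum(vapply(which(block_aligned), function(j)
    block_pat[[j]][2] - block_pat[[j]][1] + 1L, integer(1)))
  coverage <- aligned_aa / nchar(parent_protein)
  introns_in_match <- sum(block_aligned[-k] & block_aligned[-1])
  n_genomic_introns <- 0L
  idx <- which(block_aligned)
  if (length(idx) > 1)
    for (t in seq_len(length(idx) - 1L)) {
      a <- block_gpos[[idx[t]]]; b <- block_gpos[[idx[t + 1L]]]
      gap <- max(a[1], b[1]) - min(a[2], b[2]) - 1L
      if (gap > min_intron) n_genomic_introns <- n_genomic_introns + 1L
    }
  list(spliced_align_score = sum(block_score[block_aligned]) -
         intron_penalty * n_genomic_introns,
       introns_in_match = introns_in_match,
       coverage = coverage)
}

#' Full retrogene screen
#'
#' Runs the complete pipeline: six-frame translated matching of every
#' protein, adjacent-match merging (< `max_gap` nt), identity/length
#' filtering, parental assignment among multi-exon (>= 3 exon) proteins,
#' and intron-aware verification with `flank_bp` flanks. A candidate is
#' accepted iff its spliced-alignment score exceeds `min_score`, at least
#' `min_introns` parental introns fall inside the matched part of the parent,
#' and parental coverage exceeds `min_coverage` (all strict). Loci
#' overlapping their assigned parent's own annotated span are self-matches
#' and are excluded; overlapping accepted loci are deduplicated keeping the
#' best score. Verification already aligns the recruited sequence back to
#' the parent within the flanked window.
#'
#' @param proteome Named character vector of focal proteins (names = gene
#'   ids).
#' @param genome Named character vector of contigs.
#' @param models A [gene_models()] object for the annotated genes.
#' @param evalue_cutoff Translated-search E-value cutoff (default 1e-3).
#' @param max_gap Merge gap in nt (default 40).
#' @param min_identity,min_aa_length Merged-match filters (0.30 / 50 aa).
#' @param min_score Spliced-alignment acceptance score (default 35).
#' @param min_introns Minimum parental introns in the match (default 2).
#' @param min_coverage Minimum parental coverage (default 0.40, strict `>`).
#' @param flank_bp Verification flank (default 10000).
#' @param intron_penalty,min_intron See [verify_intronless()].
#' @return data.frame of accepted calls: retro_id, chrom, start, end,
#'   strand, parent_id, similarity, spliced_align_score, introns_in_match,
#'   coverage.
#' @export
call_retrogenes <- function(proteome, genome, models,
                            evalue_cutoff = 1e-3, max_gap = 40L,
                            min_identity = 0.30, min_aa_length = 50L,
                            min_score = 35, min_introns = 2L,
                            min_coverage = 0.40, flank_bp = 10000L,
                            intron_penalty = 10, min_intron = 30L) {
  frames <- genome_frames(genome)
  multi_ids <- models$genes$gene_id[models$genes$exon_count >= 3L]
  parent_proteins <- proteome[intersect(names(proteome), multi_ids)]
  cand <- list()
  for (pid in names(proteome)) {
    m <- translated_match(pid, proteome[[pid]], frames,
                          evalue_cutoff = evalue_cutoff)
    if (!nrow(m)) next
    mm <- filter_merged(merge_adjacent(m, max_gap = max_gap),
                        min_identity = min_identity,
                        min_aa_length = min_aa_length)
    # a protein always matches its own annotated locus: drop those self-hits
    own <- models$genes[models$genes$gene_id == pid, ]
    if (nrow(own))
      mm <- mm[!(mm$chrom == own$chrom & mm$start <= own$end &
                   mm$end >= own$start), , drop = FALSE]
    if (nrow(mm)) cand[[length(cand) + 1L]] <- mm
  }
  calls <- list()
  if (length(cand)) {
    cand <- do.call(rbind, cand)
    for (i in seq_len(nrow(cand))) {
      locus <- cand[i, ]
      par <- assign_parent(locus, genome, parent_proteins,
                           min_identity = min_identity)
      if (is.null(par)) next
      pg <- models$genes[models$genes$gene_id == par$parent_id, ]
      # self-match guard: a locus inside its own parent's annotation
      if (nrow(pg) && pg$chrom == locus$chrom &&
          locus$start <= pg$end && locus$end >= pg$start) next
      v <- verify_intronless(locus, genome, par$parent_id, models,
                             proteome[[par$parent_id]], flank_bp = flank_bp,
                             min_intron = min_intron,
                             intron_penalty = intron_penalty,
                             mask = pg[, c("start", "end"), drop = FALSE])
      if (v$spliced_align_score > min_score &&
          v$introns_in_match >= min_introns &&
          v$coverage > min_coverage)
        calls[[length(calls) + 1L]] <- data.frame(
          chrom = locus$chrom, start = locus$start, end = locus$end,
          strand = locus$strand, parent_id = par$parent_id,
          similarity = par$similarity,
          spliced_align_score = v$spliced_align_score,
          introns_in_match = v$introns_in_match, coverage = v$coverage,
          stringsAsFactors = FALSE)
    }
  }
  if (!length(calls))
    return(data.frame(retro_id = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), parent_id = character(0),
                      similarity = numeric(0),
                      spliced_align_score = numeric(0),
                      introns_in_match = integer(0), coverage = numeric(0)))
  calls <- do.call(rbind, calls)
  # dedupe overlapping loci: keep the best-scoring call per cluster
  gr <- GenomicRanges::GRanges(calls$chrom,
                               IRanges::IRanges(calls$start, calls$end))
  cl <- GenomicRanges::findOverlaps(gr, GenomicRanges::reduce(gr),
                                    select = "first")
  keep <- unlist(lapply(split(seq_len(nrow(calls)), cl), function(ix)
    ix[which.max(calls$spliced_align_score[ix])]))
  calls <- calls[sort(keep), , drop = FALSE]
  stopifnot(all(calls$spliced_align_score > min_score),
            all(calls$introns_in_match >= min_introns),
            all(calls$coverage > min_coverage))
  calls <- cbind(retro_id = sprintf("retro_call_%02d", seq_len(nrow(calls))),
                 calls, stringsAsFactors = FALSE)
  rownames(calls) <- NULL
  calls
}

#' Chimeric-gene calls from retrogene loci
#'
#' An annotated gene is chimeric iff its coding sequence overlaps a retro
#' locus by more than `min_overlap` bp (overlap measured on CDS/exon
#' intervals, UTRs excluded). Overlaps exceeding `fp_overlap` bp are flagged
#' `possible_false_positive` — possibly derived from the parental gene or
#' its flanks — but never removed. A gene that is itself the parent of the
#' retro locus is excluded.
#'
#' @param retro_calls data.frame from [call_retrogenes()] (needs chrom,
#'   start, end, parent_id and optionally retro_id).
#' @param models A [gene_models()] object.
#' @param min_overlap Chimera threshold in bp (default 50, strict `>`).
#' @param fp_overlap False-positive flag threshold (default 90, strict `>`).
#' @return data.frame: gene_id, retro_id, cds_overlap_bp,
#'   possible_false_positive.
#' @export
call_chimeras <- function(retro_calls, models, min_overlap = 50L,
                          fp_overlap = 90L) {
  out <- list()
  if (nrow(retro_calls)) {
    if (is.null(retro_calls$retro_id))
      retro_calls$retro_id <- sprintf("retro_call_%02d",
                                      seq_len(nrow(retro_calls)))
    ex <- models$exons
    chrom_of <- stats::setNames(models$genes$chrom, models$genes$gene_id)
    for (i in seq_len(nrow(retro_calls))) {
      rc <- retro_calls[i, ]
      locus <- IRanges::IRanges(rc$start, rc$end)
      for (gid in unique(ex$gene_id)) {
        if (!is.na(rc$parent_id) && gid == rc$parent_id) next
        if (chrom_of[[gid]] != rc$chrom) next
        ge <- ex[ex$gene_id == gid, , drop = FALSE]
        ov <- sum(IRanges::width(IRanges::intersect(
          IRanges::reduce(IRanges::IRanges(ge$start, ge$end)), locus)))
        if (ov > min_overlap)
          out[[length(out) + 1L]] <- data.frame(
            gene_id = gid, retro_id = rc$retro_id, cds_overlap_bp = ov,
            possible_false_positive = ov > fp_overlap,
            stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out))
    return(data.frame(gene_id = character(0), retro_id = character(0),
                      cds_overlap_bp = integer(0),
                      possible_false_positive = logical(0)))
  do.call(rbind, out)
}
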