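.match_row <- function(start, end, id = "p", chrom = "c", strand = "+",
                       ident = 0.9, aalen = NULL, score = 100) {
  if (is.null(aalen)) aalen <- (end - start + 1) %/% 3
  data.frame(protein_id = id, chrom = chrom, strand = strand, frame = 0L,
             start = start, end = end, aa_identity_frac = ident,
             matched_aa_length = aalen, score = score,
             stringsAsFactors = FALSE)
}

test_that("adjacent matches merge below the 40 bp gap, strictly", {
  # [100,199] and [230,299]: gap 30 -> merged
  m <- rbind(.match_row(100, 199), .match_row(230, 299))
  merged <- merge_adjacent(m, max_gap = 40L)
  expect_equal(nrow(merged), 1)
  expect_equal(c(merged$start, merged$end), c(100, 299))
  # gap exactly 40 -> not merged
  m2 <- rbind(.match_row(100, 199), .match_row(240, 309))
  expect_equal(nrow(merge_adjacent(m2, max_gap = 40L)), 2)
  # overlapping matches merge unconditionally
  m3 <- rbind(.match_row(100, 199), .match_row(150, 260))
  expect_equal(nrow(merge_adjacent(m3)), 1)
})

test_that("merging chains transitively and is idempotent and order-independent", {
  # gaps 10, 35, 39: one merged interval
  m <- rbind(.match_row(100, 199), .match_row(210, 299),
             .match_row(335, 399), .match_row(439, 500))
  merged <- merge_adjacent(m)
  expect_equal(nrow(merged), 1)
  expect_equal(c(merged$start, merged$end), c(100, 500))
  expect_equal(merge_adjacent(merged), merged)
  shuffled <- m[c(3, 1, 4, 2), ]
  expect_equal(merge_adjacent(shuffled), merged)
  # weighted identity: 30 aa at 1.0 with 30 aa at 0.5 -> 0.75
  m4 <- rbind(.match_row(100, 189, ident = 1.0),
              .match_row(200, 289, ident = 0.5))
  expect_equal(merge_adjacent(m4)$aa_identity_frac, 0.75)
})

test_that("merged-match filter applies both strict thresholds", {
  keep <- .match_row(1, 300, ident = 0.31, aalen = 51)
  expect_equal(nrow(filter_merged(keep)), 1)
  expect_equal(nrow(filter_merged(.match_row(1, 300, ident = 0.30,
                                             aalen = 200))), 0)
  expect_equal(nrow(filter_merged(.match_row(1, 300, ident = 0.90,
                                             aalen = 50))), 0)
})

test_that("translated matching recovers a planted exact copy and nothing in noise", {
  set.seed(17)
  prot <- lsgscan:::random_protein(80)
  cds <- lsgscan:::reverse_translate(prot)
  genome <- c(chrI = paste0(lsgscan:::random_dna(500), cds,
                            lsgscan:::random_dna(500)))
  m <- translated_match("p", prot, genome)
  expect_gte(nrow(m), 1)
  best <- m[which.max(m$score), ]
  expect_equal(c(best$start, best$end), c(501, 500 + nchar(cds)))
  expect_equal(best$aa_identity_frac, 1)
  # unrelated protein: no match anywhere
  other <- lsgscan:::random_protein(80)
  expect_equal(nrow(translated_match("q", other,
                                     c(chrI = lsgscan:::random_dna(2000)))), 0)
})

test_that("parent assignment picks the closest multi-exon protein deterministically", {
  set.seed(19)
  parent <- lsgscan:::random_protein(120)
  decoy <- lsgscan:::mutate_protein(parent, 0.20)
  near <- lsgscan:::mutate_protein(parent, 0.02)
  cds <- lsgscan:::reverse_translate(near)
  genome <- c(chrI = paste0(lsgscan:::random_dna(200), cds,
                            lsgscan:::random_dna(200)))
  locus <- list(chrom = "chrI", strand = "+", start = 201L,
                end = 200L + nchar(cds))
  res <- assign_parent(locus, genome, c(P1 = parent, P2 = decoy))
  expect_identical(res$parent_id, "P1")
  expect_gt(res$similarity, 0.9)
  expect_null(assign_parent(locus, genome, character(0)))
})

test_that("intron verification distinguishes retrocopies from spliced loci", {
  w <- zero_world()
  genome <- world_genome(w)
  tr <- w$truth$retro
  for (i in seq_len(nrow(tr))) {
    parent <- tr$parent_id[i]
    v <- verify_intronless(tr[i, ], genome, parent, w$models,
                           w$proteome[[parent]],
                           mask = w$models$genes[
                             w$models$genes$gene_id == parent,
                             c("start", "end")])
    k <- w$models$genes$exon_count[w$models$genes$gene_id == parent]
    expect_equal(v$introns_in_match, k - 1)   # full-length copy spans all
    expect_equal(v$coverage, 1)
    expect_gt(v$spliced_align_score, 35)
  }
})

test_that("acceptance thresholds are enforced strictly on call objects", {
  w <- zero_world()
  calls <- retro_calls_for("zero")
  expect_true(all(calls$spliced_align_score > 35))
  expect_true(all(calls$introns_in_match >= 2))
  expect_true(all(calls$coverage > 0.40))
})

test_that("planted retrogenes are recovered exactly with no false calls", {
  for (which in c("zero", "small")) {
    w <- if (which == "zero") zero_world() else small_world()
    calls <- retro_calls_for(which)
    tr <- w$truth$retro
    expect_equal(nrow(calls), nrow(tr), info = which)
    calls <- calls[order(calls$start), ]; tr <- tr[order(tr$start), ]
    expect_equal(calls$parent_id, tr$parent_id, info = which)
    # loci recovered within one codon of the planted coordinates
    expect_true(all(abs(calls$start - tr$start) <= 3), info = which)
    expect_true(all(abs(calls$end - tr$end) <= 3), info = which)
  }
})

test_that("chimera calls obey the strict >50 bp rule and the >90 bp flag", {
  models <- gene_models(
    data.frame(gene_id = c("host", "parent"), chrom = "c", strand = "+",
               start = c(1000L, 5000L), end = c(1400L, 6000L),
               exon_count = c(1L, 3L)),
    data.frame(gene_id = c("host", "parent", "parent", "parent"),
               start = c(1000L, 5000L, 5400L, 5800L),
               end = c(1400L, 5100L, 5500L, 6000L)))
  rc <- function(end) data.frame(retro_id = "r1", chrom = "c",
                                 start = 500L, end = end,
                                 parent_id = "parent")
  # CDS overlap 60: chimeric, unflagged
  res60 <- call_chimeras(rc(1059L), models)
  expect_equal(res60$gene_id, "host")
  expect_equal(res60$cds_overlap_bp, 60)
  expect_false(res60$possible_false_positive)
  # overlap 95: chimeric, flagged possible false positive
  res95 <- call_chimeras(rc(1094L), models)
  expect_true(res95$possible_false_positive)
  # overlap exactly 50: no call
  expect_equal(nrow(call_chimeras(rc(1049L), models)), 0)
  # the parent itself is never called chimeric
  res_par <- call_chimeras(data.frame(retro_id = "r2", chrom = "c",
                                      start = 5000L, end = 6000L,
                                      parent_id = "parent"), models)
  expect_false("parent" %in% res_par$gene_id)
})

test_that("planted chimeric hosts are the only chimera calls on the worlds", {
  for (which in c("zero", "small")) {
    w <- if (which == "zero") zero_world() else small_world()
    chim <- call_chimeras(retro_calls_for(which), w$models)
    truth_hosts <- w$truth$retro$chimeric_host
    truth_hosts <- truth_hosts[!is.na(truth_hosts)]
    expect_setequal(chim$gene_id, truth_hosts)
    expect_equal(chim$cds_overlap_bp,
                 rep(w$config$chimera_overlap_bp, nrow(chim)),
                 tolerance = 0.05)
  }
})
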