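.mapping <- function(tid, len = 200L, ident = 100, covm = 100, covw = 100,
                     score = len, start = 1000L, chrom = "c")
  data.frame(transcript_id = tid, chrom = chrom, strand = "+",
             mapped_start = start, mapped_end = start + len - 1L,
             mapped_length = len, identity_pct = ident,
             coverage_in_mapping_pct = covm, coverage_whole_pct = covw,
             score = score, stringsAsFactors = FALSE)

test_that("mapping filters are inclusive at all four boundaries", {
  at_bounds <- .mapping("t1", len = 150L, ident = 98, covm = 97, covw = 75)
  expect_equal(nrow(filter_mappings(at_bounds)), 1)
  expect_equal(nrow(filter_mappings(.mapping("t2", len = 149L, ident = 99,
                                             covm = 99, covw = 99))), 0)
  expect_equal(nrow(filter_mappings(.mapping("t3", ident = 97.9))), 0)
  expect_equal(nrow(filter_mappings(.mapping("t4", covm = 96.9))), 0)
  expect_equal(nrow(filter_mappings(.mapping("t5", covw = 74.9))), 0)
  # filter then resolve: both idempotent, outputs subsets of inputs
  m <- rbind(at_bounds, .mapping("t2", len = 149L))
  f <- filter_mappings(m)
  expect_equal(filter_mappings(f), f)
  r <- resolve_ambiguous(f)
  expect_equal(resolve_ambiguous(r), r)
  expect_true(all(r$transcript_id %in% m$transcript_id))
})

test_that("ambiguous multi-locus transcripts are discarded at the 2% rule", {
  two <- rbind(.mapping("t", score = 100), .mapping("t", score = 99,
                                                    start = 5000L))
  expect_equal(nrow(resolve_ambiguous(two)), 0)      # 1% < 2%: ambiguous
  clear <- rbind(.mapping("t", score = 100), .mapping("t", score = 90,
                                                      start = 5000L))
  res <- resolve_ambiguous(clear)
  expect_equal(nrow(res), 1)
  expect_equal(res$score, 100)
  single <- .mapping("t", score = 42)
  expect_equal(nrow(resolve_ambiguous(single)), 1)
  # boundary: exactly 2% difference is kept (strict <)
  edge <- rbind(.mapping("t", score = 100), .mapping("t", score = 98,
                                                     start = 5000L))
  expect_equal(nrow(resolve_ambiguous(edge)), 1)
})

test_that("EST expression needs strictly more than 100 bp of overlap", {
  gene <- data.frame(gene_id = "g", chrom = "c", start = 1000L, end = 2000L)
  expect_true(est_expressed(gene, .mapping("t", len = 101L, start = 1000L)))
  expect_false(est_expressed(gene, .mapping("t", len = 100L, start = 1000L)))
  expect_false(est_expressed(gene, .mapping("t", chrom = "other")))
})

test_that("RPKM follows its closed form and scales linearly", {
  expect_equal(rpkm(10, 1000, 1e6), 10)
  expect_equal(rpkm(0, 1000, 1e6), 0)
  expect_equal(rpkm(7, 1234, 2.5e6), 7e9 / (1234 * 2.5e6))
  expect_equal(rpkm(14, 1234, 2.5e6), 2 * rpkm(7, 1234, 2.5e6))
  expect_equal(rpkm(7, 1234, 5e6), rpkm(7, 1234, 2.5e6) / 2)
  expect_error(rpkm(1, 0, 1e6))
})

test_that("per-stage counts and expressed flags match the planted truth", {
  w <- small_world()
  expr <- expression_matrix(w$models, w$reads)
  m <- merge(expr, w$truth$expression, by = c("gene_id", "stage"))
  expect_equal(nrow(m), nrow(w$truth$expression))
  expect_identical(m$expressed.x, m$expressed.y)
  # rpkm = 0 exactly when read_count = 0
  expect_identical(expr$rpkm == 0, expr$read_count == 0)
})

test_that("stage proportions equal planted per-group prevalence", {
  w <- small_world()
  labels <- data.frame(gene_id = w$truth$genes$gene_id,
                       label = w$truth$genes$class)
  expr <- expression_matrix(w$models, w$reads)
  props <- stage_proportions(labels, expr, groups = c("SSG", "GSG", "EC"))
  tr <- merge(w$truth$expression,
              w$truth$genes[, c("gene_id", "class")], by = "gene_id")
  for (i in seq_len(nrow(props))) {
    sub <- tr[tr$stage == props$stage[i] & tr$class == props$group[i], ]
    expect_equal(props$proportion[i], mean(sub$expressed))
  }
  expect_true(all(props$proportion >= 0 & props$proportion <= 1))
})

test_that("transcript support percentages recover planted prevalence exactly", {
  w <- small_world()
  filt <- resolve_ambiguous(filter_mappings(w$mappings))
  support <- vapply(seq_len(nrow(w$models$genes)), function(i)
    est_expressed(w$models$genes[i, ], filt), logical(1))
  names(support) <- w$models$genes$gene_id
  tg <- w$truth$genes
  expect_identical(unname(support[tg$gene_id]), tg$expressed)
  feats <- feature_table(w$models, c(chrI = w$genome), w$proteome)
  gs <- group_feature_stats(feats,
                            data.frame(gene_id = tg$gene_id,
                                       label = tg$class),
                            transcript_support = support)
  for (g in c("SSG", "GSG", "EC"))
    expect_equal(gs$transcript_pct[[g]],
                 100 * mean(tg$expressed[tg$class == g]))
})

test_that("Welch t-test matches the manual formula and behaves sensibly", {
  a <- c(2.1, 3.4, 2.8, 3.9, 2.2); b <- c(4.5, 5.1, 4.8, 5.9, 4.2)
  manual_t <- (mean(a) - mean(b)) /
    sqrt(var(a) / length(a) + var(b) / length(b))
  res <- two_sample_ttest(a, b)
  expect_equal(res$t, manual_t)
  df <- (var(a) / 5 + var(b) / 5)^2 /
    ((var(a) / 5)^2 / 4 + (var(b) / 5)^2 / 4)
  expect_equal(res$p, 2 * stats::pt(abs(manual_t), df, lower.tail = FALSE))
  # identical samples
  expect_equal(two_sample_ttest(c(1, 2, 3), c(1, 2, 3)),
               list(t = 0, p = 1))
  # a constant shift at large n is detected
  set.seed(4)
  x <- stats::rnorm(200)
  expect_lt(two_sample_ttest(x, x + 1)$p, 1e-10)
})
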