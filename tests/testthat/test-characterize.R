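test_that("features follow their definitions on hand-built genes", {
  # single-exon gene spanning ATGC: GC = 50%
  models <- gene_models(
    data.frame(gene_id = "g1", chrom = "c", strand = "+", start = 1L,
               end = 4L, exon_count = 1L),
    data.frame(gene_id = "g1", start = 1L, end = 4L))
  f <- gene_features("g1", models, c(c = "ATGC"))
  expect_equal(f$gc_content_pct, 50)
  expect_equal(f$gene_length_nt, 4L)
  expect_equal(f$exon_count, 1L)

  # three exons [1,90], [191,280], [381,470]: span 470, 3 exons
  set.seed(2)
  contig <- lsgscan:::random_dna(600)
  models3 <- gene_models(
    data.frame(gene_id = "g3", chrom = "c", strand = "+", start = 1L,
               end = 470L, exon_count = 3L),
    data.frame(gene_id = "g3", start = c(1L, 191L, 381L),
               end = c(90L, 280L, 470L)))
  f3 <- gene_features("g3", models3, c(c = contig))
  expect_equal(f3$gene_length_nt, 470L)
  expect_equal(f3$exon_count, 3L)
  expect_error(gene_features("g3", models3, c(c = substr(contig, 1, 100))),
               "bounds")
})

test_that("features agree with a naive independent recomputation", {
  w <- small_world()
  gn <- c(chrI = w$genome)
  feats <- feature_table(w$models, gn, w$proteome)
  for (i in seq_len(nrow(w$models$genes))) {
    gid <- w$models$genes$gene_id[i]
    ex <- w$models$exons[w$models$exons$gene_id == gid, ]
    oracle <- naive_gene_features(w$genome, ex$start, ex$end)
    row <- feats[feats$gene_id == gid, ]
    expect_equal(row$gene_length_nt, oracle$gene_length)
    expect_equal(row$exon_count, oracle$exon_count)
    expect_equal(row$gc_content_pct, oracle$gc_pct)
    expect_equal(row$protein_length_aa, nchar(w$proteome[[gid]]))
  }
})

test_that("GC content is invariant under reverse-complement", {
  set.seed(9)
  contig <- lsgscan:::random_dna(300)
  rc <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(contig)))
  mk <- function(s) gene_models(
    data.frame(gene_id = "g", chrom = "c", strand = "+", start = 41L,
               end = 260L, exon_count = 1L),
    data.frame(gene_id = "g", start = 41L, end = 260L))
  gc_fwd <- gene_features("g", mk(contig), c(c = contig))$gc_content_pct
  # same interval counted from the other end of the reverse complement
  mk_rc <- gene_models(
    data.frame(gene_id = "g", chrom = "c", strand = "-", start = 41L,
               end = 260L, exon_count = 1L),
    data.frame(gene_id = "g", start = 41L, end = 260L))
  gc_rev <- gene_features("g", mk_rc, c(c = rc))$gc_content_pct
  expect_equal(gc_fwd, gc_rev)
})

test_that("one-way ANOVA matches hand-computed sums of squares", {
  g <- list(c(2, 3, 7, 2, 6), c(10, 8, 7, 5), c(10, 13, 14, 13))
  # manual computation: between/within sums of squares
  N <- sum(lengths(g)); k <- length(g)
  grand <- mean(unlist(g))
  ss_between <- sum(lengths(g) * (vapply(g, mean, 1) - grand)^2)
  ss_within <- sum(unlist(lapply(g, function(x) (x - mean(x))^2)))
  F_manual <- (ss_between / (k - 1)) / (ss_within / (N - k))
  res <- one_way_anova(g)
  expect_equal(res$F, F_manual)
  expect_equal(res$p, stats::pf(F_manual, k - 1, N - k, lower.tail = FALSE))
})

test_that("ANOVA degenerate and invariance properties hold", {
  # identical groups with zero variance: F defined as 0, p = 1
  expect_equal(one_way_anova(list(c(5, 5), c(5, 5), c(5, 5))),
               list(F = 0, p = 1))
  # equal means, nonzero variance: F = 0
  expect_equal(one_way_anova(list(c(1, 2, 3), c(1, 2, 3)))$F, 0)
  g <- list(c(2, 3, 7), c(10, 8, 5), c(10, 13, 14))
  base <- one_way_anova(g)$F
  shifted <- one_way_anova(lapply(g, `+`, 100))$F
  scaled <- one_way_anova(lapply(g, `*`, 3.5))$F
  expect_equal(shifted, base)
  expect_equal(scaled, base)
  expect_error(one_way_anova(list(c(1, 2))))
  expect_error(one_way_anova(list(c(1, 2), 3)))
})

test_that("group means preserve the planted size ordering EC > GSG > SSG", {
  w <- small_world()
  feats <- feature_table(w$models, c(chrI = w$genome), w$proteome)
  gs <- group_feature_stats(feats,
                            data.frame(gene_id = w$truth$genes$gene_id,
                                       label = w$truth$genes$class))
  m <- gs$stats
  for (metric in c("gene_length_nt", "protein_length_aa", "exon_count")) {
    mu <- stats::setNames(m$mean[m$metric == metric], m$group[m$metric == metric])
    expect_gt(mu[["EC"]], mu[["GSG"]])
    expect_gt(mu[["GSG"]], mu[["SSG"]])
  }
  # SE = sd/sqrt(n) spot check
  ssg_lengths <- feats$gene_length_nt[
    w$truth$genes$class[match(feats$gene_id, w$truth$genes$gene_id)] == "SSG"]
  expect_equal(m$se[m$metric == "gene_length_nt" & m$group == "SSG"],
               stats::sd(ssg_lengths) / sqrt(length(ssg_lengths)))
})
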