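test_that("matrix selection follows the length classes with inclusive bounds", {
  expect_identical(select_matrix(25), "PAM30")
  expect_identical(select_matrix(29), "PAM30")
  expect_identical(select_matrix(30), "PAM70")
  expect_identical(select_matrix(70), "PAM70")
  expect_identical(select_matrix(71), "BLOSUM62")
  expect_identical(select_matrix(100), "BLOSUM62")
  expect_error(select_matrix(0))
  expect_error(select_matrix(-5))
})

test_that("identity self-alignment scores the sum of diagonal entries", {
  sch <- scoring_scheme("BLOSUM62")
  hit <- smith_waterman("MKV", "MKV", sch)
  expected <- sch$matrix["M", "M"] + sch$matrix["K", "K"] +
    sch$matrix["V", "V"]
  expect_equal(hit$raw_score, expected)
  expect_equal(hit$identity_frac, 1)
})

test_that("no positive-scoring alignment yields no hit", {
  # BLOSUM62 scores A-C pairs negative throughout
  expect_null(smith_waterman("AAAA", "CCCC"))
})

test_that("invalid residues are rejected, X scores zero", {
  expect_error(smith_waterman("MK9", "MKV"), "invalid")
  sch <- scoring_scheme("BLOSUM62")
  with_x <- smith_waterman("MXV", "MXV", sch)
  expect_equal(with_x$raw_score,
               sch$matrix["M", "M"] + 0 + sch$matrix["V", "V"])
})

test_that("DP score equals exhaustive enumeration on small reduced-alphabet pairs", {
  sch <- scoring_scheme("BLOSUM62")
  alpha <- c("A", "C", "D", "E")
  set.seed(42)
  for (rep in 1:40) {
    la <- sample(2:6, 1); lb <- sample(2:6, 1)
    a <- paste(sample(alpha, la, replace = TRUE), collapse = "")
    b <- paste(sample(alpha, lb, replace = TRUE), collapse = "")
    oracle <- enum_local_score(a, b, sch$matrix, sch$gap_open, sch$gap_extend)
    hit <- smith_waterman(a, b, sch)
    got <- if (is.null(hit)) 0 else hit$raw_score
    expect_equal(got, oracle, info = paste(a, "vs", b))
  }
})

test_that("a pair with one mismatch and one gap matches the enumeration oracle", {
  sch <- scoring_scheme("BLOSUM62")
  a <- "MKVDEC"
  b <- "MKVWDEC"   # W inserted; alignment must open a gap
  oracle <- enum_local_score(a, b, sch$matrix, sch$gap_open, sch$gap_extend)
  expect_equal(smith_waterman(a, b, sch)$raw_score, oracle)
})

test_that("alignment score is symmetric and monotone under target extension", {
  sch <- scoring_scheme("BLOSUM62")
  set.seed(7)
  aas <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]
  for (rep in 1:10) {
    a <- paste(sample(aas, 12, replace = TRUE), collapse = "")
    b <- paste(sample(aas, 15, replace = TRUE), collapse = "")
    sa <- smith_waterman(a, b, sch); sb <- smith_waterman(b, a, sch)
    expect_equal(is.null(sa), is.null(sb))
    if (!is.null(sa)) expect_equal(sa$raw_score, sb$raw_score)
    ext <- paste0(b, paste(sample(aas, 5, replace = TRUE), collapse = ""))
    s1 <- smith_waterman(a, b, sch); s2 <- smith_waterman(a, ext, sch)
    v1 <- if (is.null(s1)) 0 else s1$raw_score
    v2 <- if (is.null(s2)) 0 else s2$raw_score
    expect_gte(v2, v1)
  }
})

test_that("E-value follows the closed form and its scaling laws", {
  sch <- scoring_scheme("BLOSUM62", lambda = 0.267, K = 0.041)
  # direct evaluation of K * m * n * exp(-lambda * S)
  expect_equal(evalue(50, 100, 10000, sch), 0.041 * 1e6 * exp(-13.35))
  # limit: huge score -> 0
  expect_equal(evalue(1e6, 100, 10000, sch), 0)
  # linearity in database size
  expect_equal(evalue(50, 100, 20000, sch), 2 * evalue(50, 100, 10000, sch))
  # strictly decreasing in score
  expect_lt(evalue(51, 100, 10000, sch), evalue(50, 100, 10000, sch))
  expect_error(evalue(50, 0, 10000, sch))
})

test_that("has_hit handles empty panels, self matches, and is monotone in cutoff", {
  q <- random_prot <- paste(rep("MKVLIDEW", 13), collapse = "")  # 104 aa
  expect_false(has_hit(q, character(0)))
  expect_true(has_hit(q, c(other = "WWWW", self = q)))
  # monotone: a hit at a stricter cutoff is a hit at a looser one
  set.seed(3)
  panel <- vapply(1:5, function(i)
    paste(sample(strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]], 80,
                 replace = TRUE), collapse = ""), character(1))
  for (q2 in panel[1:2]) {
    if (has_hit(q2, panel, cutoff = 1e-6))
      expect_true(has_hit(q2, panel, cutoff = 1e-5))
  }
})

test_that("hit tables in tabular outfmt-6 subset form are read back", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("q1\tt1\t98.5\t120\t1e-30\t250",
               "q2\tt2\t45.0\t80\t0.5\t30"), f)
  tab <- read_hit_table(f)
  expect_equal(nrow(tab), 2)
  expect_equal(tab$e_value, c(1e-30, 0.5))
  expect_equal(tab$query_id, c("q1", "q2"))
})
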