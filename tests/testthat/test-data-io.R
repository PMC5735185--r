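test_that("expression matrix TSV parsing, validation and round trip", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\ts1\ts2", "g1\t1.5\t2", "g2\t3\t4", "g3\t5\t6.25"),
             path)
  m <- read_expression_matrix(path, "log2_intensity")
  expect_equal(dim(m), c(3L, 2L))
  expect_equal(rownames(m), c("g1", "g2", "g3"))
  expect_equal(unclass(m)["g3", "s2"], 6.25)

  # duplicate sample header is rejected by name
  writeLines(c("gene_id\ts1\ts1", "g1\t1\t2"), path)
  expect_error(read_expression_matrix(path), "s1")

  # non-numeric cell names row and column
  writeLines(c("gene_id\ts1\ts2", "g1\t1\tx"), path)
  expect_error(read_expression_matrix(path), "g1.*s2")

  # write -> read reproduces values exactly
  m0 <- make_em(matrix(c(0.1, -2.5, 3.75, 4, 5.5, pi), 3, 2))
  p2 <- withr::local_tempfile(fileext = ".tsv")
  write_expression_matrix(m0, p2)
  m1 <- read_expression_matrix(p2, "log2_intensity")
  expect_equal(unclass(m1), unclass(m0), tolerance = 1e-12)
})

test_that("expression matrix constructor enforces its invariants", {
  v <- matrix(1:4, 2, 2, dimnames = list(c("g1", "g1"), c("s1", "s2")))
  expect_error(expr_matrix(v * 1.0, "counts"), "duplicate gene")
  v2 <- matrix(c(1, 2, 3, -4), 2, 2,
               dimnames = list(c("g1", "g2"), c("s1", "s2")))
  expect_error(expr_matrix(v2, "counts"), "non-negative")
  v2[2, 2] <- Inf
  expect_error(expr_matrix(v2, "log2_intensity"), "finite")
})

test_that("signature files parse, deduplicate and validate", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tdirection", "a\tup", "b\tup", "c\tup",
               "d\tdown", "e\tdown"), path)
  sig <- read_signature(path, name = "toy")
  expect_length(sig$up, 3)
  expect_length(sig$down, 2)

  writeLines(c("gene_id\tdirection", "a\tup", "a\tup", "b\tdown"), path)
  expect_warning(sig2 <- read_signature(path), "duplicated")
  expect_equal(sig2$up, "a")

  writeLines(c("gene_id\tdirection", "a\tup", "a\tdown"), path)
  expect_error(read_signature(path), "both up and down")

  expect_error(gene_signature("empty", up = character()), "empty")

  # round trip
  p2 <- withr::local_tempfile(fileext = ".tsv")
  write_signature(sig, p2)
  expect_equal(read_signature(p2)$up, sig$up)
})

test_that("GMT collections read and write", {
  path <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("SET_A\tdesc a\tg1\tg2\tg3", "SET_B\t-\tg2\tg4"), path)
  sets <- read_gmt(path)
  expect_length(sets, 2)
  expect_equal(sets$SET_A, c("g1", "g2", "g3"))
  expect_equal(sets$SET_B, c("g2", "g4"))
  p2 <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(sets, p2)
  expect_equal(read_gmt(p2)$SET_B, c("g2", "g4"))
})

test_that("probe collapse averages probe rows per gene", {
  m <- make_em(matrix(c(1, 3, 5, 2, 4, 6), 3, 2),
               genes = c("p1", "p2", "p3"))
  pm <- c(p1 = "G", p2 = "G", p3 = "H")
  out <- collapse_probes(m, pm)
  expect_equal(unclass(out)["G", ], c(s1 = 2, s2 = 3))   # mean(1,3), mean(2,4)
  expect_equal(unclass(out)["H", ], c(s1 = 5, s2 = 6))   # untouched single probe
  expect_equal(rownames(out), c("G", "H"))               # lexicographic

  m3 <- make_em(matrix(c(0, 0, 6), 3, 1), genes = c("p1", "p2", "p3"))
  expect_equal(unname(unclass(collapse_probes(m3, c(p1 = "G", p2 = "G", p3 = "G")))[1, 1]), 2)

  expect_error(collapse_probes(m, c(p1 = "G")), "p2")
})

test_that("quantile normalisation matches hand values, is idempotent, handles ties", {
  m <- make_em(matrix(c(1, 2, 3, 4, 5, 6), 3, 2))
  q <- quantile_normalize(m)
  expect_equal(unname(unclass(q)[, 1]), c(2.5, 3.5, 4.5))
  expect_equal(unname(unclass(q)[, 2]), c(2.5, 3.5, 4.5))

  # identical columns unchanged
  m2 <- make_em(matrix(c(1, 5, 2, 1, 5, 2), 3, 2))
  expect_equal(unclass(quantile_normalize(m2)), unclass(m2))

  # idempotence and identical sorted columns (exact on tie-free data; a tied
  # block is replaced by its block mean, which perturbs the shared reference)
  set.seed(7)
  vals <- matrix(rnorm(60, 7), 12, 5)
  m3 <- make_em(vals)
  q1 <- quantile_normalize(m3)
  q2 <- quantile_normalize(q1)
  expect_equal(unclass(q2), unclass(q1), tolerance = 1e-12)
  sorted <- apply(unclass(q1), 2, sort)
  expect_true(all(abs(sorted - sorted[, 1]) < 1e-12))
  # within-column rank order preserved
  expect_equal(order(unclass(q1)[, 2]), order(vals[, 2]))

  # tie rule: tied values share the mean of the reference values at the
  # ranks they occupy
  mt <- make_em(matrix(c(1, 1, 5,
                         2, 4, 6), 3, 2))
  qt <- unclass(quantile_normalize(mt))
  ref <- c(mean(c(1, 2)), mean(c(1, 4)), mean(c(5, 6)))  # (1.5, 2.5, 5.5)
  expect_equal(unname(qt[, 1]), c(2, 2, 5.5))            # mean(ref[1:2]) twice
  expect_equal(unname(qt[, 2]), ref)

  expect_warning(quantile_normalize(make_em(matrix(1:3, 3, 1) * 1.0)),
                 "single-sample")
  expect_error(quantile_normalize(make_em(matrix(1:6, 3, 2) * 1.0, "counts")),
               "log2_intensity")
})

test_that("quantile normalisation agrees with the limma reference on tie-free data", {
  # (tie handling differs by convention: this package averages the reference
  # values over the occupied ranks, limma interpolates at mean ranks; the
  # two coincide whenever columns are tie-free)
  skip_if_not_installed("limma")
  set.seed(11)
  vals <- matrix(rnorm(200, 8, 2), 40, 5)
  m <- make_em(vals)
  ours <- unclass(quantile_normalize(m))
  ref <- limma::normalizeQuantiles(vals, ties = TRUE)
  expect_equal(unname(ours[, ]), unname(ref), tolerance = 1e-10)
})

test_that("probe collapse + quantile normalisation commute with column permutation", {
  set.seed(3)
  vals <- matrix(rnorm(80, 7), 20, 4)
  m <- make_em(vals, genes = sprintf("p%02d", 1:20))
  pm <- setNames(sprintf("G%02d", rep(1:10, each = 2)), sprintf("p%02d", 1:20))
  perm <- c(3, 1, 4, 2)
  strip <- function(m) { a <- unclass(m); attr(a, "scale") <- NULL; a }
  ref <- quantile_normalize(collapse_probes(m, pm))
  m_perm <- make_em(vals[, perm], genes = sprintf("p%02d", 1:20),
                    samples = colnames(m)[perm])
  out <- quantile_normalize(collapse_probes(m_perm, pm))
  expect_equal(strip(out), strip(ref)[, perm], tolerance = 1e-12)
})

test_that("size-factor normalisation: hand cases, scaling property, DESeq2 agreement", {
  # identical columns -> both factors 1
  m <- make_em(matrix(c(2, 3, 4, 2, 3, 4), 3, 2), scale = "counts")
  expect_equal(unname(size_factor_normalize(m)$size_factors), c(1, 1))

  # column2 = 2 * column1 -> factors (1/sqrt(2), sqrt(2)); log-product 0
  m2 <- make_em(matrix(c(1, 2, 4, 2, 4, 8), 3, 2), scale = "counts")
  sf <- size_factor_normalize(m2)$size_factors
  expect_equal(unname(sf), c(1 / sqrt(2), sqrt(2)), tolerance = 1e-12)
  expect_equal(sum(log(sf)), 0, tolerance = 1e-12)
  expect_equal(expr_scale(size_factor_normalize(m2)$matrix),
               "log2_normalised_counts")

  # the factors are relative to the geometric-mean pseudo-reference, so a
  # whole-matrix rescale leaves them unchanged, while scaling one column by c
  # multiplies that column's factor *relative to the others* by exactly c
  set.seed(5)
  base <- matrix(rpois(60, 50) + 1, 20, 3)
  sf0 <- size_factor_normalize(make_em(base * 1.0, scale = "counts"))$size_factors
  sf_all <- size_factor_normalize(make_em(base * 3.0, scale = "counts"))$size_factors
  expect_equal(unname(sf_all), unname(sf0), tolerance = 1e-10)
  scaled <- base; scaled[, 2] <- scaled[, 2] * 4
  sf1 <- size_factor_normalize(make_em(scaled * 1.0, scale = "counts"))$size_factors
  expect_equal(unname(sf1[2] / sf1[1]), unname(4 * sf0[2] / sf0[1]),
               tolerance = 1e-10)

  # every gene containing a zero -> no reference genes
  m0 <- make_em(matrix(c(0, 1, 1, 0), 2, 2), scale = "counts")
  expect_error(size_factor_normalize(m0), "reference")

  skip_if_not_installed("DESeq2")
  ref <- DESeq2::estimateSizeFactorsForMatrix(base)
  expect_equal(unname(sf0), unname(ref), tolerance = 1e-10)
})

test_that("sample tables validate ids, groups and per-study composition", {
  df <- data.frame(sample_id = c("a", "b", "c", "d"),
                   study_id = c("s1", "s1", "s2", "s2"),
                   group = c("case", "control", "case", "control"))
  expect_silent(sample_table(df, require_both_groups = TRUE))
  df2 <- df; df2$group[2] <- "healthy"
  expect_error(sample_table(df2), "healthy")
  df3 <- df; df3$sample_id[2] <- "a"
  expect_error(sample_table(df3), "duplicate")
  df4 <- df; df4$group <- c("case", "case", "case", "control")
  expect_error(sample_table(df4, require_both_groups = TRUE), "at least one")
})
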