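test_that("Mann-Whitney exact branch matches enumeration and hand values", {
  expect_equal(mann_whitney_u(c(4, 5, 6), c(1, 2, 3))$p_value, 0.1)
  expect_equal(mann_whitney_u(c(1, 4), c(2, 3))$p_value, 1)
  expect_equal(mann_whitney_u(c(2, 2, 2), c(2, 2, 2))$p_value, 1)

  set.seed(31)
  for (i in 1:40) {
    n1 <- sample(2:6, 1); n2 <- sample(2:6, 1)
    x <- sample(seq(0, 1, length.out = 50), n1)  # distinct values, no ties
    y <- sample(setdiff(seq(0, 1, length.out = 50), x), n2)
    expect_equal(mann_whitney_u(x, y)$p_value, enumerate_mwu_p(x, y),
                 tolerance = 1e-9)
  }
})

test_that("Mann-Whitney approximate branch tracks wilcox.test and the exact branch", {
  set.seed(32)
  # tie-corrected normal approximation vs wilcox.test on tied data
  for (i in 1:20) {
    x <- sample(1:6, 15, replace = TRUE); y <- sample(2:7, 18, replace = TRUE)
    ours <- mann_whitney_u(x, y)
    ref <- suppressWarnings(wilcox.test(x, y, correct = TRUE, exact = FALSE))
    expect_false(ours$exact)
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-9)
  }
  # exact and approximate branches stay close over an exhaustive tie-free
  # sweep of all group sizes with 6 <= n1 + n2 <= 12 (worst case sits just
  # under 0.05, at the smallest group sizes)
  worst <- 0
  for (n1 in 2:6) for (n2 in 2:6) {
    if (n1 + n2 < 6 || n1 + n2 > 12) next
    combs <- utils::combn(n1 + n2, n1)
    us <- apply(combs, 2, function(idx) sum(idx) - n1 * (n1 + 1) / 2)
    for (u in unique(us)) {
      x <- combs[, match(u, us)]
      y <- setdiff(seq_len(n1 + n2), x)
      p_exact <- mann_whitney_u(x, y, exact_max = 12)$p_value
      p_approx <- mann_whitney_u(x, y, exact_max = 0)$p_value
      worst <- max(worst, abs(p_exact - p_approx))
    }
  }
  expect_lt(worst, 0.05)
})

test_that("study effects reproduce hand-computed forest rows", {
  sc <- data.frame(sample_id = letters[1:4], study_id = "s1",
                   group = c("case", "case", "control", "control"),
                   z_score = c(0.5, 1.5, -0.5, -1.5))
  se <- study_effect(sc, "s1")
  expect_equal(se$effect, 2)
  expect_equal(se$se, sqrt(0.5 / 2 + 0.5 / 2), tolerance = 1e-9)
  expect_equal(c(se$ci_lo, se$ci_hi), c(0.614, 3.386), tolerance = 1e-3)
  expect_true(se$ci_lo <= se$effect && se$effect <= se$ci_hi)

  # equal group means -> effect 0
  sc0 <- sc; sc0$z_score <- c(1, -1, 1, -1)
  expect_equal(study_effect(sc0, "s1")$effect, 0)

  # zero within-group variance -> degenerate CI flagged
  scd <- sc; scd$z_score <- c(1, 1, -1, -1)
  expect_warning(sed <- study_effect(scd, "s1"), "degenerate")
  expect_equal(sed$effect, 2)
  expect_equal(sed$se, 0)

  expect_error(study_effect(sc[2:4, ], "s1"), ">=2")
})

test_that("DerSimonian-Laird pooling matches hand cases and metafor", {
  # single study: identity
  r1 <- dersimonian_laird(1.3, 0.4)
  expect_equal(r1$pooled_effect, 1.3)
  expect_equal(r1$pooled_se, 0.4)
  expect_equal(r1$tau2, 0)

  # homogeneous pair
  r2 <- dersimonian_laird(c(1, 1), c(0.5, 0.5))
  expect_equal(r2$Q, 0)
  expect_equal(r2$tau2, 0)
  expect_equal(r2$pooled_effect, 1)
  expect_equal(r2$pooled_se, 1 / sqrt(8), tolerance = 1e-9)  # prints as 0.3536

  # heterogeneous pair, hand-derived
  r3 <- dersimonian_laird(c(0, 2), c(1, 1))
  expect_equal(r3$Q, 2)
  expect_equal(r3$tau2, 1)
  expect_equal(r3$pooled_effect, 1)
  expect_equal(r3$pooled_se, 1)

  expect_error(dersimonian_laird(numeric(0), numeric(0)), "no studies")
  expect_error(dersimonian_laird(c(1, 2), c(0.5, 0)), "positive")

  # fixed-effects reduction whenever Q <= k-1
  set.seed(41)
  for (i in 1:20) {
    k <- sample(2:6, 1)
    e <- rnorm(k, 1, 0.05); s <- runif(k, 0.3, 0.6)
    r <- dersimonian_laird(e, s)
    if (r$Q <= k - 1) {
      w <- 1 / s^2
      expect_equal(r$pooled_effect, sum(w * e) / sum(w), tolerance = 1e-12)
      expect_equal(r$pooled_se, 1 / sqrt(sum(w)), tolerance = 1e-12)
    }
  }

  skip_if_not_installed("metafor")
  set.seed(42)
  for (i in 1:10) {
    k <- sample(2:8, 1)
    e <- rnorm(k, 0.5, 1); s <- runif(k, 0.2, 1)
    ours <- dersimonian_laird(e, s)
    ref <- metafor::rma(yi = e, sei = s, method = "DL")
    expect_equal(ours$pooled_effect, as.numeric(ref$beta), tolerance = 1e-9)
    expect_equal(ours$pooled_se, ref$se, tolerance = 1e-9)
    expect_equal(ours$tau2, ref$tau2, tolerance = 1e-9)
  }
})

test_that("Fisher's combined test: identities, closed form, monotonicity", {
  expect_equal(fisher_combined(0.05)$p_value, 0.05, tolerance = 1e-12)
  r <- fisher_combined(c(0.1, 0.1))
  expect_equal(r$chi2, -2 * (log(0.1) + log(0.1)), tolerance = 1e-9)
  expect_equal(r$df, 4)
  expect_equal(r$p_value, exp(-r$chi2 / 2) * (1 + r$chi2 / 2), tolerance = 1e-12)
  expect_equal(fisher_combined(c(1, 1, 1))$p_value, 1)
  expect_warning(r0 <- fisher_combined(c(0.5, 0)), "0")
  expect_equal(r0$p_value, 0)
  expect_error(fisher_combined(numeric(0)), "no p-values")

  # decreasing any input p decreases the combined p
  set.seed(43)
  for (i in 1:20) {
    p <- runif(5, 0.05, 1)
    j <- sample(5, 1)
    p2 <- p; p2[j] <- p2[j] * 0.5
    expect_lt(fisher_combined(p2)$p_value, fisher_combined(p)$p_value)
  }
})

test_that("combined p-values are calibrated under a global score null", {
  set.seed(44)
  reps <- 200
  p <- replicate(reps, {
    per_study <- vapply(1:5, function(s) {
      z <- rnorm(12)
      mann_whitney_u(z[1:6], z[7:12])$p_value
    }, 0)
    fisher_combined(per_study)$p_value
  })
  frac <- mean(p < 0.05)
  bounds <- qbinom(c(0.005, 0.995), reps, 0.05) / reps
  expect_gte(frac, bounds[1])
  expect_lte(frac, bounds[2])
})

test_that("meta_analyze assembles forest, pooling and combined test", {
  sim <- tiny_cohort(effect_delta = 1.5, seed = 5)
  sc <- score_studies(sim$matrices, sim$samples, sim$signature)
  ma <- meta_analyze(sc)
  expect_equal(nrow(ma$per_study), 2)
  expect_equal(ma$meta$k, 2)
  expect_equal(ma$meta$fisher_df, 4)
  expect_lt(ma$meta$pooled_effect, 0)     # repression scenario
  expect_lt(ma$meta$fisher_p, 0.05)
  expect_true(ma$meta$ci_lo <= ma$meta$pooled_effect &&
              ma$meta$pooled_effect <= ma$meta$ci_hi)
  # effect-based p-values are an alternative source, same pooling
  ma2 <- meta_analyze(sc, p_source = "effect")
  expect_equal(ma2$meta$pooled_effect, ma$meta$pooled_effect)
  expect_lt(ma2$meta$fisher_p, 0.05)
})
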