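#' Two-sided Mann-Whitney U test (Wilcoxon rank-sum)
#'
#' Exact two-sided p-value from the null distribution of the U statistic when
#' the combined sample size is at most `exact_max` and there are no ties
#' (doubling rule: `p = min(1, 2 min(P(U <= u), P(U >= u)))`); otherwise the
#' normal approximation with continuity correction and tie-corrected
#' variance. If every value across both groups is identical, p = 1.
#'
#' @param x,y numeric score vectors (cases, controls).
#' @param exact_max largest `length(x) + length(y)` for the exact branch
#'   (default 12).
#' @return list with `u` (U statistic of `x`), `p_value`, and `exact` flag.
#' @export
mann_whitney_u <- function(x, y, exact_max = 12) {
  n1 <- length(x); n2 <- length(y)
  if (n1 < 1L || n2 < 1L) stop("both groups must be non-empty")
  all_vals <- c(x, y)
  r <- rank(all_vals)
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- anyDuplicated(all_vals) > 0L
  if (length(unique(all_vals)) == 1L)
    return(list(u = u, p_value = 1, exact = FALSE))
  if (!ties && n1 + n2 <= exact_max) {
    p_le <- stats::pwilcox(u, n1, n2)
    p_ge <- 1 - stats::pwilcox(u - 1, n1, n2)
    p <- min(1, 2 * min(p_le, p_ge))
    return(list(u = u, p_value = p, exact = TRUE))
  }
  n <- n1 + n2
  mu <- n1 * n2 / 2
  tie_tab <- table(all_vals)
  sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(tie_tab^3 - tie_tab) / (n * (n - 1)))
  z <- (u - mu - sign(u - mu) * 0.5) / sqrt(sigma2)
  list(u = u, p_value = 2 * stats::pnorm(-abs(z)), exact = FALSE)
}

#' Per-study effect of case status on z-normalised scores
#'
#' For one study, the effect is the difference of group means of z-scores
#' (case minus control), with the unequal-variance standard error
#' `sqrt(s2_case/n_case + s2_control/n_control)`, a normal-theory 95% CI, and
#' a two-sided Mann-Whitney p-value — one row of a forest table.
#'
#' @param scores a z-normalised score table ([znorm_within_study()]).
#' @param study_id which study to summarise.
#' @return one-row data frame: `study_id`, `n_case`, `n_control`, `effect`,
#'   `se`, `ci_lo`, `ci_hi`, `wilcoxon_p`.
#' @export
study_effect <- function(scores, study_id) {
  s <- scores[scores$study_id == study_id, ]
  zc <- s$z_score[s$group == "case"]; zn <- s$z_score[s$group == "control"]
  if (length(zc) < 2L || length(zn) < 2L)
    stop("study '", study_id, "' needs >=2 cases and >=2 controls")
  eff <- mean(zc) - mean(zn)
  se <- sqrt(stats::var(zc) / length(zc) + stats::var(zn) / length(zn))
  if (se == 0) warning("study '", study_id, "': zero standard error; ",
                       "confidence interval degenerate")
  zcrit <- stats::qnorm(0.975)
  data.frame(study_id = study_id, n_case = length(zc), n_control = length(zn),
             effect = eff, se = se,
             ci_lo = eff - zcrit * se, ci_hi = eff + zcrit * se,
             wilcoxon_p = mann_whitney_u(zc, zn)$p_value,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' @rdname study_effect
#' @return [study_effects()]: one row per study (the forest table).
#' @export
study_effects <- function(scores) {
  do.call(rbind, lapply(unique(scores$study_id), study_effect, scores = scores))
}

#' DerSimonian-Laird random-effects pooling
#'
#' Classic method-of-moments random-effects meta-analysis: fixed weights
#' `w = 1/se^2` give Cochran's Q; the between-study variance is
#' `tau2 = max(0, (Q - (k-1)) / (sum(w) - sum(w^2)/sum(w)))`; random-effects
#' weights `1/(se^2 + tau2)` give the pooled estimate, its SE and a
#' normal-based 95% CI. With a single study the pooled estimate is that
#' study's effect and tau2 is 0. When Q <= k-1 the estimator reduces to
#' inverse-variance fixed-effects pooling.
#'
#' @param effects numeric vector of study effects.
#' @param ses their standard errors (all > 0).
#' @return list of class `"meta_result"`: `k`, `pooled_effect`, `pooled_se`,
#'   `ci_lo`, `ci_hi`, `tau2`, `Q`.
#' @export
dersimonian_laird <- function(effects, ses) {
  k <- length(effects)
  if (k == 0L) stop("no studies to pool")
  if (length(ses) != k) stop("effects and ses must have equal length")
  if (any(ses <= 0)) stop("all standard errors must be positive")
  w <- 1 / ses^2
  e_fixed <- sum(w * effects) / sum(w)
  Q <- sum(w * (effects - e_fixed)^2)
  tau2 <- if (k == 1L) 0 else {
    C <- sum(w) - sum(w^2) / sum(w)
    max(0, (Q - (k - 1)) / C)
  }
  ws <- 1 / (ses^2 + tau2)
  pooled <- sum(ws * effects) / sum(ws)
  pse <- 1 / sqrt(sum(ws))
  zcrit <- stats::qnorm(0.975)
  structure(list(k = k, pooled_effect = pooled, pooled_se = pse,
                 ci_lo = pooled - zcrit * pse, ci_hi = pooled + zcrit * pse,
                 tau2 = tau2, Q = Q),
            class = "meta_result")
}

#' Fisher's combined probability test
#'
#' Combines independent per-study p-values: `chi2 = -2 sum(log p)` is
#' chi-square with `2k` degrees of freedom under the global null. A p of
#' exactly 0 makes the statistic infinite; the combined p is then returned as
#' 0 with a warning.
#'
#' @param p numeric vector of p-values in (0, 1].
#' @return list: `chi2`, `df`, `p_value`.
#' @export
fisher_combined <- function(p) {
  if (length(p) == 0L) stop("no p-values to combine")
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  if (any(p == 0)) {
    warning("p-value of 0 supplied; combined chi-square is infinite, p = 0")
    return(list(chi2 = Inf, df = 2 * length(p), p_value = 0))
  }
  chi2 <- -2 * sum(log(p))
  df <- 2 * length(p)
  list(chi2 = chi2, df = df,
       p_value = stats::pchisq(chi2, df = df, lower.tail = FALSE))
}

#' Full cross-study meta-analysis of a score table
#'
#' Builds the per-study forest table ([study_effects()]), pools the effects
#' by DerSimonian-Laird, and combines per-study p-values with Fisher's test.
#' By default the combined test consumes the per-study Wilcoxon p-values
#' (matching the per-study significance tests); `p_source = "effect"`
#' switches to normal-theory p-values of the effect estimates.
#'
#' @param scores a z-normalised score table.
#' @param p_source `"wilcoxon"` (default) or `"effect"`.
#' @return list of class `"meta_analysis"`: `per_study` (forest data frame)
#'   and `meta` (a `meta_result` extended with `fisher_chi2`, `fisher_df`,
#'   `fisher_p`).
#' @export
meta_analyze <- function(scores, p_source = c("wilcoxon", "effect")) {
  p_source <- match.arg(p_source)
  per <- study_effects(scores)
  res <- dersimonian_laird(per$effect, per$se)
  p <- if (p_source == "wilcoxon") per$wilcoxon_p
       else 2 * stats::pnorm(-abs(per$effect / per$se))
  fc <- fisher_combined(p)
  res$fisher_chi2 <- fc$chi2
  res$fisher_df <- fc$df
  res$fisher_p <- fc$p_value
  structure(list(per_study = per, meta = res), class = "meta_analysis")
}

#' @export
print.meta_result <- function(x, ...) {
  cat(sprintf("random-effects pooling of %d studies\n", x$k))
  cat(sprintf("  pooled effect %.4f (SE %.4f, 95%% CI %.4f to %.4f)\n",
              x$pooled_effect, x$pooled_se, x$ci_lo, x$ci_hi))
  cat(sprintf("  tau2 %.4f, Q %.4f\n", x$tau2, x$Q))
  if (!is.null(x$fisher_p))
    cat(sprintf("  Fisher's combined: chi2 %.4f on %d df, p %.3g\n",
                x$fisher_chi2, x$fisher_df, x$fisher_p))
  invisible(x)
}

#' @export
print.meta_analysis <- function(x, ...) {
  print(x$per_study)
  print(x$meta)
  invisible(x)
}
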