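#' ROC curve and AUC for a score vector
#'
#' Computes the full ROC curve and the area under it, with ties counted one
#' half: `auc = (#(case > control) + 0.5 #(case == control)) /
#' (n_case * n_control)`, the Mann-Whitney probability estimate. The score
#' orientation is an explicit argument, never inferred from the data:
#' `"case-high"` for signatures whose score rises in cases (activated-target
#' means), `"case-low"` for repression-style scores that fall in cases.
#' Internally scores are sign-flipped so that higher always predicts case.
#'
#' @param scores numeric vector.
#' @param labels character/factor vector along `scores` with values
#'   `"case"`/`"control"`; both classes must be present.
#' @param direction `"case-high"` or `"case-low"`.
#' @return list of class `"roc_result"`: `thresholds`, `fpr`, `tpr`
#'   (monotone from (0,0) to (1,1)), `auc`, `direction`, `n_case`,
#'   `n_control`.
#' @export
roc_curve <- function(scores, labels, direction = c("case-high", "case-low")) {
  direction <- match.arg(direction)
  labels <- as.character(labels)
  if (!all(labels %in% c("case", "control")))
    stop("labels must be 'case'/'control'")
  is_case <- labels == "case"
  if (!any(is_case) || all(is_case)) stop("need both classes present")
  s <- if (direction == "case-low") -scores else scores
  ord <- order(s, decreasing = TRUE)
  s_ord <- s[ord]; case_ord <- is_case[ord]
  # one curve point per distinct threshold value
  keep <- !duplicated(s_ord, fromLast = TRUE) | seq_along(s_ord) == length(s_ord)
  cum_tp <- cumsum(case_ord); cum_fp <- cumsum(!case_ord)
  n1 <- sum(is_case); n0 <- sum(!is_case)
  last <- which(keep)
  tpr <- c(0, cum_tp[last] / n1); fpr <- c(0, cum_fp[last] / n0)
  r <- rank(s)
  auc <- (sum(r[is_case]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  structure(list(thresholds = c(Inf, s_ord[last]), fpr = fpr, tpr = tpr,
                 auc = auc, direction = direction,
                 n_case = n1, n_control = n0),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC (%s, %d cases / %d controls): AUC = %.4f\n",
              x$direction, x$n_case, x$n_control, x$auc))
  invisible(x)
}

# DeLong placement values: for each case, fraction of controls it beats
# (ties half); and symmetrically for controls.
delong_placements <- function(scores, is_case) {
  xs <- scores[is_case]; ys <- scores[!is_case]
  v10 <- vapply(xs, function(x) mean((x > ys) + 0.5 * (x == ys)), 0)
  v01 <- vapply(ys, function(y) mean((xs > y) + 0.5 * (xs == y)), 0)
  list(v10 = v10, v01 = v01, auc = mean(v10))
}

#' DeLong's test for two paired (correlated) AUCs
#'
#' Nonparametric comparison of the AUCs of two score vectors measured on the
#' same samples. Variances and the covariance of the AUC estimates come from
#' the empirical variance of the per-case and per-control placement values;
#' `z = (auc_1 - auc_2) / sqrt(var_diff)` is compared to the standard
#' normal, two-sided. If the variance of the difference is zero and the AUCs
#' are equal (e.g. comparing a score with itself), p = 1.
#'
#' @param scores_a,scores_b numeric vectors on the *same* samples, same order.
#' @param labels `"case"`/`"control"` vector along the scores.
#' @param direction_a,direction_b score orientation per marker, see
#'   [roc_curve()].
#' @return list of class `"delong_result"`: `auc_1`, `auc_2`, `var_diff`,
#'   `z_stat`, `p_value`.
#' @export
delong_paired <- function(scores_a, scores_b, labels,
                          direction_a = "case-high",
                          direction_b = "case-high") {
  if (length(scores_a) != length(scores_b))
    stop("paired comparison requires scores on the same samples ",
         "(lengths differ); use separate single-AUC analyses otherwise")
  labels <- as.character(labels)
  if (!all(labels %in% c("case", "control")))
    stop("labels must be 'case'/'control'")
  is_case <- labels == "case"
  if (!any(is_case) || all(is_case)) stop("need both classes present")
  a <- if (direction_a == "case-low") -scores_a else scores_a
  b <- if (direction_b == "case-low") -scores_b else scores_b
  pa <- delong_placements(a, is_case); pb <- delong_placements(b, is_case)
  m <- sum(is_case); n <- sum(!is_case)
  s10 <- stats::cov(cbind(pa$v10, pb$v10))  # 2x2, among cases
  s01 <- stats::cov(cbind(pa$v01, pb$v01))  # 2x2, among controls
  S <- s10 / m + s01 / n
  var_diff <- S[1, 1] + S[2, 2] - 2 * S[1, 2]
  d <- pa$auc - pb$auc
  if (var_diff <= 0) {
    if (abs(d) < .Machine$double.eps^0.5)
      return(structure(list(auc_1 = pa$auc, auc_2 = pb$auc, var_diff = 0,
                            z_stat = 0, p_value = 1), class = "delong_result"))
    stop("zero variance of the AUC difference with unequal AUCs")
  }
  z <- d / sqrt(var_diff)
  structure(list(auc_1 = pa$auc, auc_2 = pb$auc, var_diff = var_diff,
                 z_stat = z, p_value = 2 * stats::pnorm(-abs(z))),
            class = "delong_result")
}

#' @export
print.delong_result <- function(x, ...) {
  cat(sprintf("DeLong paired AUC comparison: %.4f vs %.4f, z = %.3f, p = %.4g\n",
              x$auc_1, x$auc_2, x$z_stat, x$p_value))
  invisible(x)
}
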