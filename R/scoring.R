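#' Single-sample score: mean expression of the up-target genes
#'
#' The simplest single-sample signature score, used for activated-target
#' signatures: for each sample, the arithmetic mean of the expression of the
#' signature's up genes present in the matrix. The down set is ignored. Genes
#' absent from the matrix are excluded from the mean but reported in the
#' matched-gene counts.
#'
#' @param m an `expr_matrix` (any log scale).
#' @param sig a `gene_signature`.
#' @param min_genes minimum number of matched up genes required (default 10);
#'   fewer is an error, never a silent near-empty mean.
#' @return data frame with columns `sample_id`, `raw_score`,
#'   `n_up_matched`, `n_down_matched`.
#' @export
mean_target_score <- function(m, sig, min_genes = 10) {
  up <- intersect(sig$up, rownames(m))
  if (length(up) < min_genes)
    stop("signature '", sig$name, "': only ", length(up), " of ",
         length(sig$up), " up genes matched; need >= ", min_genes)
  data.frame(sample_id = colnames(m),
             raw_score = colMeans(unclass(m)[up, , drop = FALSE]),
             n_up_matched = length(up),
             n_down_matched = length(intersect(sig$down, rownames(m))),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Single-sample score: t-statistic contrasting up- vs down-target genes
#'
#' For each sample, the two-sample t statistic comparing the expression of
#' the signature's up genes against its down genes *within that sample*.
#' Positive scores mean the up targets sit above the down targets. The
#' default is the Welch (unequal-variance) statistic, robust to unequal set
#' sizes and spreads; `variance = "pooled"` is available for sensitivity
#' analysis.
#'
#' @inheritParams mean_target_score
#' @param min_genes minimum matched genes required in *each* of the up and
#'   down sets (default 10).
#' @param variance `"welch"` (default) or `"pooled"`.
#' @return data frame as in [mean_target_score()].
#' @export
up_down_t_score <- function(m, sig, min_genes = 10,
                            variance = c("welch", "pooled")) {
  variance <- match.arg(variance)
  up <- intersect(sig$up, rownames(m))
  down <- intersect(sig$down, rownames(m))
  if (length(up) < min_genes || length(down) < min_genes)
    stop("signature '", sig$name, "': matched ", length(up), " up / ",
         length(down), " down genes; need >= ", min_genes, " in each set")
  U <- unclass(m)[up, , drop = FALSE]; D <- unclass(m)[down, , drop = FALSE]
  g1 <- length(up); g2 <- length(down)
  mu <- colMeans(U); md <- colMeans(D)
  vu <- colSums(sweep(U, 2L, mu)^2) / (g1 - 1)
  vd <- colSums(sweep(D, 2L, md)^2) / (g2 - 1)
  se2 <- if (variance == "welch") vu / g1 + vd / g2
         else (((g1 - 1) * vu + (g2 - 1) * vd) / (g1 + g2 - 2)) * (1 / g1 + 1 / g2)
  score <- (mu - md) / sqrt(se2)
  degen <- vu == 0 & vd == 0
  if (any(degen)) {
    warning(sum(degen), " sample(s) with zero variance in both gene groups; ",
            "score set to 0")
    score[degen] <- 0
  }
  data.frame(sample_id = colnames(m), raw_score = unname(score),
             n_up_matched = g1, n_down_matched = g2,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' z-normalise raw signature scores within each study
#'
#' Centres and scales the raw scores per study (cases and controls together;
#' sd with the n-1 denominator), so that scores from different platforms and
#' cohorts are comparable and can be pooled. For matched designs
#' (patient/control pairs z-scored per pair), pass the pairing identifier as
#' `study_id` in the metadata — the grouping variable is the only thing that
#' changes.
#'
#' @param scores data frame from a scoring function (columns `sample_id`,
#'   `raw_score`, ...).
#' @param meta a [sample_table()] data frame covering every scored sample.
#' @return a score table: `scores` joined with `study_id` and `group`, plus a
#'   `z_score` column. Within each study the z-scores have mean 0, sd 1.
#' @export
znorm_within_study <- function(scores, meta) {
  meta <- sample_table(meta)
  missing <- setdiff(scores$sample_id, meta$sample_id)
  if (length(missing))
    stop("scored samples absent from metadata: ", paste(missing, collapse = ", "))
  idx <- match(scores$sample_id, meta$sample_id)
  out <- scores
  out$study_id <- meta$study_id[idx]
  out$group <- meta$group[idx]
  if ("pairing_id" %in% names(meta)) out$pairing_id <- meta$pairing_id[idx]
  out$z_score <- NA_real_
  for (s in unique(out$study_id)) {
    i <- out$study_id == s
    if (sum(i) < 2L)
      stop("study '", s, "' has a single scored sample; z-score undefined")
    mu <- mean(out$raw_score[i]); sd <- stats::sd(out$raw_score[i])
    if (sd == 0) stop("study '", s, "' has zero score variance; z-score undefined")
    out$z_score[i] <- (out$raw_score[i] - mu) / sd
  }
  cols <- c("sample_id", "study_id", "group",
            intersect("pairing_id", names(out)),
            "raw_score", "z_score", "n_up_matched", "n_down_matched")
  out[, intersect(cols, names(out))]
}

#' Score a multi-study collection and z-normalise in one call
#'
#' Convenience wrapper: applies a scoring method to each study's matrix,
#' binds the per-study score tables, and z-normalises within study.
#'
#' @param matrices named list of `expr_matrix` objects, one per study; names
#'   are study ids matching `meta$study_id`.
#' @param meta a [sample_table()] data frame.
#' @param sig a `gene_signature`.
#' @param method `"updown-t"` (default) or `"mean"`.
#' @param min_genes passed to the scoring function.
#' @return a z-normalised score table over all studies.
#' @export
score_studies <- function(matrices, meta, sig,
                          method = c("updown-t", "mean"), min_genes = 10) {
  method <- match.arg(method)
  if (is.null(names(matrices)) || any(!nzchar(names(matrices))))
    stop("`matrices` must be a named list (names = study ids)")
  scorer <- if (method == "mean") mean_target_score else up_down_t_score
  raw <- do.call(rbind, lapply(matrices, scorer, sig = sig,
                               min_genes = min_genes))
  rownames(raw) <- NULL
  znorm_within_study(raw, meta)
}
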