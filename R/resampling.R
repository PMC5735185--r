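#' Draw a random matched-size signature from a gene universe
#'
#' Samples `n_up + n_down` genes without replacement and splits them into
#' disjoint up and down sets — the building block of the random-gene-set
#' null for signature biomarkers.
#'
#' @param universe character vector of candidate gene ids.
#' @param n_up,n_down set sizes.
#' @param name signature name.
#' @param seed optional integer; when supplied the draw is reproducible.
#' @return a `gene_signature`.
#' @export
random_signature <- function(universe, n_up, n_down, name = "random",
                             seed = NULL) {
  universe <- unique(as.character(universe))
  if (length(universe) < n_up + n_down)
    stop("universe of ", length(universe), " genes too small for ",
         n_up, " + ", n_down)
  if (!is.null(seed)) set.seed(seed)
  picked <- sample(universe, n_up + n_down)
  gene_signature(name, up = picked[seq_len(n_up)],
                 down = picked[n_up + seq_len(n_down)],
                 provenance = "random matched-size draw")
}

#' Random-gene-set null distribution for the meta-analysis pipeline
#'
#' The resampling null for a signature biomarker: repeatedly draw a random
#' signature of matched size from the genes measured in *every* study, score
#' each study with the up-vs-down t score, z-normalise within study, run the
#' per-study Mann-Whitney tests, combine them with Fisher's test, and record
#' the combined p. The observed biomarker's empirical significance uses the
#' +1 correction, `(1 + #(null p <= observed p)) / (n_iter + 1)`, so it can
#' never be exactly zero. Iterations use independent substreams expanded
#' from the master seed, so the result depends only on the seed.
#'
#' @param matrices named list of per-study `expr_matrix` objects.
#' @param meta a [sample_table()] covering all samples.
#' @param n_up,n_down matched signature sizes.
#' @param n_iter number of random draws (>= 1).
#' @param alpha significance level counted by `n_significant`.
#' @param seed master integer seed.
#' @param observed_fisher_p optional combined p of the observed biomarker;
#'   when given, `empirical_p` is computed.
#' @param min_genes passed to [up_down_t_score()].
#' @return list of class `"null_distribution"`: `n_iter`, `seed`,
#'   `fisher_p` (vector), `alpha`, `n_significant`, and `empirical_p`
#'   (NA when no observed p was supplied).
#' @export
null_meta_distribution <- function(matrices, meta, n_up, n_down,
                                   n_iter = 1000, alpha = 0.05, seed = 1,
                                   observed_fisher_p = NULL, min_genes = 10) {
  if (length(matrices) < 1L) stop("need at least one study matrix")
  if (n_iter < 1L) stop("n_iter must be >= 1")
  universe <- Reduce(intersect, lapply(matrices, rownames))
  if (length(universe) == 0L)
    stop("gene universe (intersection across studies) is empty")
  set.seed(seed)
  iter_seeds <- sample.int(.Machine$integer.max - 1L, n_iter)
  fisher_p <- vapply(seq_len(n_iter), function(i) {
    sig <- random_signature(universe, n_up, n_down,
                            name = paste0("null_", i), seed = iter_seeds[i])
    sc <- score_studies(matrices, meta, sig, method = "updown-t",
                        min_genes = min_genes)
    p <- vapply(unique(sc$study_id), function(s) {
      d <- sc[sc$study_id == s, ]
      mann_whitney_u(d$z_score[d$group == "case"],
                     d$z_score[d$group == "control"])$p_value
    }, 0)
    fisher_combined(p)$p_value
  }, 0)
  emp <- if (is.null(observed_fisher_p)) NA_real_
         else (1 + sum(fisher_p <= observed_fisher_p)) / (n_iter + 1)
  structure(list(n_iter = n_iter, seed = seed, fisher_p = fisher_p,
                 alpha = alpha, n_significant = sum(fisher_p < alpha),
                 empirical_p = emp),
            class = "null_distribution")
}

#' @export
print.null_distribution <- function(x, ...) {
  cat(sprintf("random-signature null: %d iterations (seed %d)\n",
              x$n_iter, x$seed))
  cat(sprintf("  %d / %d combined p < %g", x$n_significant, x$n_iter, x$alpha))
  if (!is.na(x$empirical_p))
    cat(sprintf("; observed biomarker empirical p = %.4g", x$empirical_p))
  cat("\n")
  invisible(x)
}
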