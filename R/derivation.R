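#' Two-group differential expression on a log-scale matrix
#'
#' A gene-wise two-group engine for deriving target-gene signatures from
#' over-expression experiments: per gene, the log2 fold change is the
#' difference of group means (treated minus control) and the test statistic
#' is either the Welch t (default) or, with `shrink_variance = TRUE`, a
#' moderated t in which the gene-wise pooled variances are shrunk toward a
#' common prior by empirical Bayes (the prior is fitted by moment-matching
#' the log sample variances to a scaled-F model, via [limma::squeezeVar()]),
#' with the prior degrees of freedom added to the residual ones. Two-sided
#' p-values come from the t distribution; q-values are Benjamini-Hochberg.
#'
#' Genes with zero variance in both groups cannot be tested: their p-value is
#' set to 0 when the means differ and 1 otherwise, with a warning.
#'
#' @param m an `expr_matrix` on a log scale (`log2_intensity` or
#'   `log2_normalised_counts`).
#' @param groups character vector along `colnames(m)` giving each sample's
#'   group; must take exactly the two values `treated` and `control`.
#' @param treated,control the group labels to contrast.
#' @param shrink_variance use empirical-Bayes variance shrinkage instead of
#'   the Welch statistic.
#' @return data frame of class `"de_result"` with columns `gene_id`,
#'   `log2_fc`, `t_stat`, `p_value`, `q_value`, in the row order of `m`.
#' @export
two_group_de <- function(m, groups, treated = "treated", control = "control",
                         shrink_variance = FALSE) {
  if (expr_scale(m) == "counts")
    stop("two_group_de needs a log-scale matrix; normalise counts first ",
         "(size_factor_normalize)")
  if (length(groups) != ncol(m))
    stop("`groups` must have one entry per sample")
  i1 <- which(groups == treated); i2 <- which(groups == control)
  if (length(i1) + length(i2) != ncol(m))
    stop("groups contains labels other than '", treated, "'/'", control, "'")
  if (length(i1) < 2L || length(i2) < 2L)
    stop("need >=2 samples per group (treated: ", length(i1),
         ", control: ", length(i2), ")")
  x1 <- unclass(m)[, i1, drop = FALSE]; x2 <- unclass(m)[, i2, drop = FALSE]
  n1 <- ncol(x1); n2 <- ncol(x2)
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  v1 <- rowSums((x1 - m1)^2) / (n1 - 1)
  v2 <- rowSums((x2 - m2)^2) / (n2 - 1)
  fc <- m1 - m2

  if (shrink_variance) {
    df_res <- n1 + n2 - 2
    s2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / df_res
    sq <- limma::squeezeVar(s2, df = df_res)
    se <- sqrt(sq$var.post * (1 / n1 + 1 / n2))
    # cap total df at the pooled residual df, as moderated-t engines do
    df_tot <- min(df_res + sq$df.prior, nrow(m) * df_res)
    tt <- fc / se
    p <- 2 * stats::pt(-abs(tt), df = df_tot)
  } else {
    se2 <- v1 / n1 + v2 / n2
    tt <- fc / sqrt(se2)
    df_w <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
    p <- 2 * stats::pt(-abs(tt), df = df_w)
  }

  degen <- (v1 == 0 & v2 == 0)
  if (any(degen)) {
    warning(sum(degen), " gene(s) with zero variance in both groups; ",
            "p set to 0 (means differ) or 1 (means equal)")
    p[degen] <- ifelse(fc[degen] != 0, 0, 1)
    tt[degen] <- ifelse(fc[degen] != 0, sign(fc[degen]) * Inf, 0)
  }

  structure(data.frame(gene_id = rownames(m), log2_fc = fc, t_stat = tt,
                       p_value = p, q_value = bh_fdr(p),
                       row.names = NULL, stringsAsFactors = FALSE),
            class = c("de_result", "data.frame"))
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up adjustment `q(i) = min_{j>=i} p(j) * n / j` on sorted p-values,
#' mapped back to input order and capped at 1 (the `"BH"` method of
#' [stats::p.adjust()]).
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return q-values in input order; empty input gives empty output.
#' @export
bh_fdr <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Select up-regulated targets by the single-threshold rule
#'
#' The selection rule for activated targets of a strong transcriptional
#' activator: genes with log2 fold change above `fc_thresh` and FDR below
#' `fdr_thresh` (both strict inequalities) form the up set; the down set is
#' empty.
#'
#' @param de a `de_result` from [two_group_de()].
#' @param fc_thresh log2 fold-change threshold (default 2).
#' @param fdr_thresh FDR threshold (default 0.05).
#' @param name signature name.
#' @return a `gene_signature` with empty down set.
#' @export
select_targets_single <- function(de, fc_thresh = 2, fdr_thresh = 0.05,
                                  name = "activated_targets") {
  if (nrow(de) == 0L) stop("empty differential-expression result")
  up <- de$gene_id[de$log2_fc > fc_thresh & de$q_value < fdr_thresh]
  if (length(up) == 0L)
    stop("no targets at thresholds (log2 FC > ", fc_thresh,
         ", FDR < ", fdr_thresh, ")")
  gene_signature(name, up = up,
                 provenance = sprintf("single-threshold rule: log2FC > %g, FDR < %g",
                                      fc_thresh, fdr_thresh))
}

#' Select induced and repressed targets with a dominant-negative construct
#'
#' The dual-construct rule: a gene is *induced* if it goes up under
#' over-expression of the factor and down under the dominant-negative fusion
#' (DNA-binding domain + engrailed repressor), each with p below `p_thresh`;
#' *repressed* targets are the mirror image. The default `dn_rule =
#' "strict-sign"` requires the dominant-negative fold change to cross the
#' negated threshold (`fc_dn < -fc_thresh` for induced genes), matching the
#' verbal definition "suppressed by the dominant negative"; `"literal"`
#' instead applies the threshold as printed (`fc_dn < fc_thresh`), which also
#' admits genes with small dominant-negative fold changes. The ambiguity is
#' documented rather than resolved; strict-sign is the default.
#'
#' @param de_oe `de_result` for the over-expression arm vs control.
#' @param de_dn `de_result` for the dominant-negative arm vs control; must
#'   share the gene universe with `de_oe`.
#' @param fc_thresh log2 fold-change threshold (default 1).
#' @param p_thresh p-value threshold (default 0.05; unadjusted, per the rule).
#' @param dn_rule `"strict-sign"` or `"literal"` (see Details).
#' @param name signature name.
#' @return a `gene_signature` with both up (induced) and down (repressed) sets.
#' @export
select_targets_dual <- function(de_oe, de_dn, fc_thresh = 1, p_thresh = 0.05,
                                dn_rule = c("strict-sign", "literal"),
                                name = "dual_construct_targets") {
  dn_rule <- match.arg(dn_rule)
  common <- intersect(de_oe$gene_id, de_dn$gene_id)
  if (length(common) == 0L)
    stop("over-expression and dominant-negative results share no genes")
  oe <- de_oe[match(common, de_oe$gene_id), ]
  dn <- de_dn[match(common, de_dn$gene_id), ]
  dn_lo <- if (dn_rule == "strict-sign") -fc_thresh else fc_thresh
  dn_hi <- if (dn_rule == "strict-sign")  fc_thresh else -fc_thresh
  up <- common[oe$log2_fc >  fc_thresh & oe$p_value < p_thresh &
               dn$log2_fc <  dn_lo     & dn$p_value < p_thresh]
  down <- common[oe$log2_fc < -fc_thresh & oe$p_value < p_thresh &
                 dn$log2_fc >  dn_hi     & dn$p_value < p_thresh]
  if (length(up) == 0L)
    stop("no induced targets at thresholds (log2 FC > ", fc_thresh,
         ", p < ", p_thresh, ", rule ", dn_rule, ")")
  gene_signature(name, up = up, down = down,
                 provenance = sprintf(
                   "dual-construct rule: |log2FC| > %g, p < %g, dn_rule=%s",
                   fc_thresh, p_thresh, dn_rule))
}
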