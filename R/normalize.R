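#' Collapse probe-level rows to gene-level rows by averaging
#'
#' Probes (or transcript sequences) mapping to the same gene identifier are
#' averaged, the convention used when matching array probes to unique gene
#' ids before cross-platform scoring. Output genes are ordered
#' lexicographically for determinism.
#'
#' @param m an `expr_matrix` whose rownames are probe ids.
#' @param probe_map named character vector (`map[probe_id] == gene_id`);
#'   every row of `m` must be mapped.
#' @return an `expr_matrix` with one row per gene id, same scale.
#' @export
collapse_probes <- function(m, probe_map) {
  unmapped <- setdiff(rownames(m), names(probe_map))
  if (length(unmapped))
    stop("probes without a gene mapping: ", paste(unmapped, collapse = ", "))
  genes <- probe_map[rownames(m)]
  sums <- rowsum(unclass(m), group = genes, reorder = TRUE)
  n <- as.vector(table(genes)[rownames(sums)])
  out <- sums / n
  as_expr(out[order(rownames(out)), , drop = FALSE], expr_scale(m))
}

#' Quantile-normalise a log-intensity matrix across samples
#'
#' Forces every sample (column) to share the same empirical distribution: the
#' reference distribution is the vector of row means of the column-sorted
#' matrix, and each column's values are replaced by the reference values at
#' their ranks. Tied values within a column receive the mean of the reference
#' values at the ranks they jointly occupy, so within-column rank order is
#' preserved and the transform is idempotent.
#'
#' @param m an `expr_matrix` on the `log2_intensity` scale.
#' @return quantile-normalised `expr_matrix` (same scale).
#' @export
quantile_normalize <- function(m) {
  if (expr_scale(m) != "log2_intensity")
    stop("quantile_normalize expects scale 'log2_intensity', got '",
         expr_scale(m), "'")
  if (ncol(m) < 2L) {
    warning("single-sample matrix: quantile normalisation is a no-op")
    return(m)
  }
  x <- unclass(m)
  ref <- rowMeans(apply(x, 2L, sort))
  out <- apply(x, 2L, function(col) {
    res <- numeric(length(col))
    res[order(col)] <- ref
    # ties: average the reference values over the tied positions
    stats::ave(res, match(col, col), FUN = mean)
  })
  dimnames(out) <- dimnames(x)
  as_expr(out, "log2_intensity")
}

#' Median-of-ratios size-factor normalisation for count matrices
#'
#' Computes one size factor per sample as the median, over genes with a
#' positive geometric mean across samples, of the ratio of the sample's count
#' to that geometric mean; divides counts by the factors; and returns
#' `log2(normalised + 1)` values. This is the standard library-size
#' correction for RNA-seq count matrices.
#'
#' @param m an `expr_matrix` with `scale = "counts"`.
#' @return list with `matrix` (an `expr_matrix`, scale
#'   `"log2_normalised_counts"`) and `size_factors` (named numeric).
#' @export
size_factor_normalize <- function(m) {
  if (expr_scale(m) != "counts")
    stop("size_factor_normalize expects scale 'counts', got '", expr_scale(m), "'")
  x <- unclass(m)
  log_geo <- rowMeans(log(x))          # -Inf for any gene with a zero
  ref <- is.finite(log_geo)
  if (!any(ref))
    stop("no reference genes: every gene has a zero count in some sample")
  sf <- apply(x[ref, , drop = FALSE], 2L, function(col)
    exp(stats::median(log(col) - log_geo[ref])))
  norm <- sweep(x, 2L, sf, "/")
  list(matrix = as_expr(log2(norm + 1), "log2_normalised_counts"),
       size_factors = sf)
}
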