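#' Construct an expression matrix with a declared measurement scale
#'
#' The package's central container is a plain numeric matrix (genes in rows,
#' samples in columns) carrying a `scale` attribute that declares how the
#' values are to be interpreted: `"log2_intensity"` for microarray-like data,
#' `"counts"` for raw RNA-seq-like integer counts, and
#' `"log2_normalised_counts"` for counts after size-factor normalisation and
#' log transform. Downstream operations check the scale rather than guessing.
#'
#' @param values numeric matrix with unique, non-empty rownames (gene ids)
#'   and colnames (sample ids); all values finite, and non-negative when
#'   `scale = "counts"`.
#' @param scale one of `"log2_intensity"`, `"counts"`,
#'   `"log2_normalised_counts"`.
#' @return the matrix, classed `"expr_matrix"`, with attribute `scale`.
#' @examples
#' m <- expr_matrix(matrix(rnorm(6, 7), 3, 2,
#'                  dimnames = list(paste0("g", 1:3), c("s1", "s2"))),
#'                  scale = "log2_intensity")
#' expr_scale(m)
#' @export
expr_matrix <- function(values,
                        scale = c("log2_intensity", "counts",
                                  "log2_normalised_counts")) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  gid <- rownames(values); sid <- colnames(values)
  if (is.null(gid) || is.null(sid))
    stop("expression matrix needs rownames (gene ids) and colnames (sample ids)")
  if (anyDuplicated(gid))
    stop("duplicate gene ids: ", paste(unique(gid[duplicated(gid)]), collapse = ", "))
  if (anyDuplicated(sid))
    stop("duplicate sample ids: ", paste(unique(sid[duplicated(sid)]), collapse = ", "))
  if (!all(is.finite(values)))
    stop("expression values must all be finite")
  if (scale == "counts" && any(values < 0))
    stop("counts must be non-negative")
  attr(values, "scale") <- scale
  class(values) <- c("expr_matrix", class(values))
  values
}

#' @rdname expr_matrix
#' @param m an `expr_matrix`.
#' @export
expr_scale <- function(m) {
  s <- attr(m, "scale")
  if (is.null(s)) stop("matrix has no declared scale; use expr_matrix()")
  s
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d genes x %d samples [%s]\n",
              nrow(x), ncol(x), expr_scale(x)))
  invisible(x)
}

# internal: rebuild class/attr after matrix surgery
as_expr <- function(values, scale) {
  class(values) <- setdiff(class(values), "expr_matrix")
  attr(values, "scale") <- NULL
  expr_matrix(values, scale)
}

#' Construct a gene signature (up- and down-regulated target sets)
#'
#' A signature is a named pair of gene-id sets. The up set must be non-empty;
#' the down set may be empty (signatures built only from activated targets,
#' like the DUX4-style lists). The two sets must be disjoint. Duplicates
#' within a direction are removed with a warning.
#'
#' @param name character scalar.
#' @param up,down character vectors of gene ids.
#' @param provenance free-text description of where the sets came from.
#' @return a list of class `"gene_signature"` with elements
#'   `name`, `up`, `down`, `provenance`.
#' @export
gene_signature <- function(name, up, down = character(), provenance = "") {
  up <- as.character(up); down <- as.character(down)
  if (anyDuplicated(up) || anyDuplicated(down)) {
    warning("duplicated gene ids within a direction were removed")
    up <- unique(up); down <- unique(down)
  }
  if (length(up) == 0L) stop("signature '", name, "': up-gene set is empty")
  both <- intersect(up, down)
  if (length(both) > 0L)
    stop("genes listed both up and down: ", paste(both, collapse = ", "))
  structure(list(name = as.character(name), up = up, down = down,
                 provenance = as.character(provenance)),
            class = "gene_signature")
}

#' @export
print.gene_signature <- function(x, ...) {
  cat(sprintf("gene_signature '%s': %d up, %d down\n",
              x$name, length(x$up), length(x$down)))
  invisible(x)
}

#' Validate a sample metadata table
#'
#' Checks that a data frame of sample annotations satisfies the contract used
#' throughout the package: unique `sample_id`; `group` limited to
#' `"case"`/`"control"`; optional `pairing_id` for matched designs.
#'
#' @param df data frame with columns `sample_id`, `study_id`, `group` and
#'   optionally `pairing_id`.
#' @param require_both_groups if `TRUE`, every study must contain at least one
#'   case and one control (needed before effect estimation).
#' @return the validated data frame (character columns, extra columns kept).
#' @export
sample_table <- function(df, require_both_groups = FALSE) {
  need <- c("sample_id", "study_id", "group")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("sample table lacks columns: ", paste(miss, collapse = ", "))
  df$sample_id <- as.character(df$sample_id)
  df$study_id  <- as.character(df$study_id)
  df$group     <- as.character(df$group)
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample ids: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  bad <- setdiff(unique(df$group), c("case", "control"))
  if (length(bad)) stop("group must be 'case' or 'control'; found: ",
                        paste(bad, collapse = ", "))
  if (require_both_groups) {
    tab <- table(df$study_id, df$group)
    ok <- all(c("case", "control") %in% colnames(tab)) &&
      all(tab[, "case"] >= 1) && all(tab[, "control"] >= 1)
    if (!ok) stop("every study must contain at least one case and one control")
  }
  df
}
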