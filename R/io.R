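#' Read a gene-by-sample expression matrix from tab-separated text
#'
#' Expected layout: a header row of sample ids, first column gene (or probe)
#' ids, tab separation. Row order is preserved. Duplicate gene-id rows are
#' rejected; probe-level data with repeated target genes should be read with
#' probe ids and collapsed afterwards with [collapse_probes()].
#'
#' @param path file path.
#' @param scale declared measurement scale, see [expr_matrix()].
#' @return an `expr_matrix`.
#' @export
read_expression_matrix <- function(path,
                                   scale = c("log2_intensity", "counts",
                                             "log2_normalised_counts")) {
  scale <- match.arg(scale)
  header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  if (length(header) < 2L)
    stop("malformed header in ", path, ": need an id column plus >=1 sample")
  samples <- header[-1]
  dup <- unique(samples[duplicated(samples)])
  if (length(dup))
    stop("duplicate sample id in header of ", path, ": ",
         paste(dup, collapse = ", "))
  df <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                          colClasses = "character", stringsAsFactors = FALSE)
  ids <- df[[1]]
  vals <- as.matrix(df[, -1, drop = FALSE])
  num <- suppressWarnings(apply(vals, 2L, as.numeric))
  if (!is.matrix(num)) num <- matrix(num, nrow = nrow(vals), dimnames = dimnames(vals))
  bad <- which(is.na(num) & !is.na(vals), arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop(sprintf("non-numeric cell at row '%s', column '%s' in %s",
                 ids[bad[1, 1]], samples[bad[1, 2]], path))
  dimnames(num) <- list(ids, samples)
  expr_matrix(num, scale)
}

#' Write an expression matrix as tab-separated text
#'
#' @param m an `expr_matrix`.
#' @param path output file path.
#' @param id_column header name for the gene-id column.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(m, path, id_column = "gene_id") {
  df <- data.frame(rownames(m), unclass(m)[, , drop = FALSE],
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[1] <- id_column
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a two-column signature file
#'
#' The interchange format is a TSV with header `gene_id<TAB>direction`,
#' direction in `up`/`down`.
#'
#' @param path file path.
#' @param name signature name (defaults to the file stem).
#' @param provenance free text recorded on the signature.
#' @return [read_signature()]: a `gene_signature`.
#' @export
read_signature <- function(path, name = NULL, provenance = paste("read from", path)) {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  if (!all(c("gene_id", "direction") %in% names(df)))
    stop("signature file needs columns gene_id, direction: ", path)
  bad <- setdiff(unique(df$direction), c("up", "down"))
  if (length(bad)) stop("direction must be up/down; found: ", paste(bad, collapse = ", "))
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  gene_signature(name,
                 up = df$gene_id[df$direction == "up"],
                 down = df$gene_id[df$direction == "down"],
                 provenance = provenance)
}

#' @rdname read_signature
#' @param sig a `gene_signature`.
#' @export
write_signature <- function(sig, path) {
  df <- data.frame(gene_id = c(sig$up, sig$down),
                   direction = rep(c("up", "down"),
                                   c(length(sig$up), length(sig$down))),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a GMT gene-set collection
#'
#' GMT lines are `name<TAB>description<TAB>member1<TAB>member2...`.
#'
#' @param path file path.
#' @return named list of character vectors (unique members); set descriptions
#'   in attribute `"description"`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- vapply(parts, length, 1L) < 3L
  if (any(short))
    stop("GMT line(s) with fewer than 3 fields in ", path, ": line ",
         paste(which(short), collapse = ", "))
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[[`, "", 1L)
  if (anyDuplicated(names(sets)))
    stop("duplicate gene-set names in ", path)
  attr(sets, "description") <- vapply(parts, `[[`, "", 2L)
  sets
}

#' Write a named list of gene sets as GMT
#' @param sets named list of character vectors.
#' @param path output file path.
#' @param descriptions optional character vector, recycled to length(sets).
#' @export
write_gmt <- function(sets, path, descriptions = "") {
  descriptions <- rep_len(descriptions, length(sets))
  lines <- mapply(function(nm, d, g) paste(c(nm, d, g), collapse = "\t"),
                  names(sets), descriptions, sets)
  writeLines(lines, path)
  invisible(path)
}

#' Read a sample metadata table (TSV)
#'
#' Columns `sample_id`, `study_id`, `group` (case/control), optional
#' `pairing_id`.
#' @param path file path.
#' @param require_both_groups see [sample_table()].
#' @export
read_sample_table <- function(path, require_both_groups = FALSE) {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                          colClasses = "character")
  sample_table(df, require_both_groups = require_both_groups)
}

#' Read a probe-to-gene map (two-column TSV: probe_id, gene_id)
#' @param path file path.
#' @return named character vector: `map[probe_id] == gene_id`.
#' @export
read_probe_map <- function(path) {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (ncol(df) < 2L) stop("probe map needs two columns (probe_id, gene_id)")
  if (anyDuplicated(df[[1]]))
    stop("probe mapped more than once: ",
         paste(unique(df[[1]][duplicated(df[[1]])]), collapse = ", "))
  stats::setNames(df[[2]], df[[1]])
}
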