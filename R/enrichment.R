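#' One-sided over-representation test for a gene set
#'
#' Hypergeometric upper-tail (Fisher's exact) test of the overlap between a
#' query gene set and an annotated gene set, within an explicit measured-gene
#' universe: `p = P(X >= n_overlap)` for
#' `X ~ Hypergeom(n_universe, n_set, n_query)`. The universe is a required
#' argument — it should be the genes measured on the platform the query was
#' derived from, never defaulted to the union of the collection. The odds
#' ratio comes from the 2x2 table, with the Haldane 0.5 correction when a
#' cell is zero.
#'
#' @param query character vector of query gene ids (must lie in `universe`).
#' @param gene_set character vector; intersected with `universe` first.
#' @param universe character vector of measured genes.
#' @param set_name label carried into the output row.
#' @return one-row data frame: `set_name`, `n_overlap`, `n_set`, `n_query`,
#'   `n_universe`, `p_value`, `odds_ratio`.
#' @export
fisher_enrichment <- function(query, gene_set, universe, set_name = "set") {
  universe <- unique(as.character(universe))
  if (length(universe) == 0L) stop("empty universe")
  query <- unique(as.character(query))
  if (length(query) == 0L) stop("empty query set")
  outside <- setdiff(query, universe)
  if (length(outside))
    stop("query genes outside the universe: ", paste(outside, collapse = ", "))
  gs <- intersect(unique(as.character(gene_set)), universe)
  k <- length(intersect(query, gs))
  N <- length(universe); K <- length(gs); n <- length(query)
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  a <- k; b <- n - k; c <- K - k; d <- N - K - (n - k)
  if (any(c(a, b, c, d) == 0)) { a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5 }
  data.frame(set_name = set_name, n_overlap = k, n_set = K, n_query = n,
             n_universe = N, p_value = p, odds_ratio = (a * d) / (b * c),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Over-representation analysis of a query set against a GMT collection
#'
#' Applies [fisher_enrichment()] to every set in a collection and adjusts the
#' p-values across the collection by Benjamini-Hochberg ([bh_fdr()]).
#'
#' @param query character vector of gene ids.
#' @param collection named list of gene sets (e.g. from [read_gmt()]).
#' @param universe measured-gene universe.
#' @param top optional: keep only the `top` rows after sorting by p then q
#'   (the "top enriched sets" reporting convention).
#' @return data frame of class `"enrichment_table"`, one row per set, with a
#'   `q_value` column; sorted by p-value when `top` is given.
#' @export
enrich_collection <- function(query, collection, universe, top = NULL) {
  if (is.null(names(collection)))
    stop("collection must be a named list of gene sets")
  rows <- do.call(rbind, lapply(names(collection), function(nm)
    fisher_enrichment(query, collection[[nm]], universe, set_name = nm)))
  rows$q_value <- bh_fdr(rows$p_value)
  if (!is.null(top)) {
    rows <- rows[order(rows$p_value, rows$q_value), ]
    rows <- utils::head(rows, top)
    rownames(rows) <- NULL
  }
  structure(rows, class = c("enrichment_table", "data.frame"))
}

#' Robust inverse-enrichment pairing of UP/DN gene-set halves
#'
#' Many curated collections split a phenotype's genes into an "_UP" and a
#' "_DN" half. A phenotype is called *robust* for a signature when the
#' signature's activated targets and repressed targets are significantly
#' enriched in *opposite* halves: activated in UP with repressed in DN
#' ("signature activates phenotype"), or activated in DN with repressed in
#' UP ("signature represses phenotype"), both p-values below `alpha`.
#'
#' @param enr_up enrichment table for the signature's activated (up) targets.
#' @param enr_down enrichment table for the repressed (down) targets; must
#'   cover the same set names.
#' @param alpha significance level (nominal p by default; pass tables and set
#'   `use_q = TRUE` to gate on BH q-values instead).
#' @param suffix_up,suffix_dn regexes identifying the two halves of a pair.
#' @param use_q gate on `q_value` instead of `p_value`.
#' @return data frame of `RobustPair` rows: `base_name`, `up_member`,
#'   `down_member`, the four p-values (`p_act_up`, `p_act_dn`, `p_rep_up`,
#'   `p_rep_dn`), their `-log10` transforms, and `direction`. Zero rows (with
#'   a warning) when no UP/DN pairs exist.
#' @export
robust_inverse_pairs <- function(enr_up, enr_down, alpha = 0.05,
                                 suffix_up = "_UP$", suffix_dn = "_DN$",
                                 use_q = FALSE) {
  pcol <- if (use_q) "q_value" else "p_value"
  get_p <- function(tab, set) {
    i <- match(set, tab$set_name)
    if (is.na(i)) NA_real_ else tab[[pcol]][i]
  }
  names_all <- union(enr_up$set_name, enr_down$set_name)
  ups <- grep(suffix_up, names_all, value = TRUE)
  base_up <- sub(suffix_up, "", ups)
  dns <- grep(suffix_dn, names_all, value = TRUE)
  base_dn <- sub(suffix_dn, "", dns)
  bases <- intersect(base_up, base_dn)
  if (length(bases) == 0L) {
    warning("no UP/DN-paired set names found")
    return(data.frame(base_name = character(), up_member = character(),
                      down_member = character(), p_act_up = numeric(),
                      p_act_dn = numeric(), p_rep_up = numeric(),
                      p_rep_dn = numeric(), direction = character(),
                      stringsAsFactors = FALSE))
  }
  rows <- lapply(bases, function(b) {
    up_m <- ups[match(b, base_up)]; dn_m <- dns[match(b, base_dn)]
    p_act_up <- get_p(enr_up, up_m);   p_act_dn <- get_p(enr_up, dn_m)
    p_rep_up <- get_p(enr_down, up_m); p_rep_dn <- get_p(enr_down, dn_m)
    activates <- isTRUE(p_act_up < alpha) && isTRUE(p_rep_dn < alpha)
    represses <- isTRUE(p_act_dn < alpha) && isTRUE(p_rep_up < alpha)
    if (!activates && !represses) return(NULL)
    data.frame(base_name = b, up_member = up_m, down_member = dn_m,
               p_act_up = p_act_up, p_act_dn = p_act_dn,
               p_rep_up = p_rep_up, p_rep_dn = p_rep_dn,
               direction = if (activates) "signature activates phenotype"
                           else "signature represses phenotype",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(base_name = character(), up_member = character(),
                      down_member = character(), p_act_up = numeric(),
                      p_act_dn = numeric(), p_rep_up = numeric(),
                      p_rep_dn = numeric(), direction = character(),
                      stringsAsFactors = FALSE))
  for (cc in c("p_act_up", "p_act_dn", "p_rep_up", "p_rep_dn"))
    out[[paste0("neglog10_", cc)]] <- -log10(out[[cc]])
  rownames(out) <- NULL
  out
}
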