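#' Run the full biomarker analysis graph on a study collection
#'
#' Orchestrates the public operations of the package end to end: score each
#' signature in every study, z-normalise within study, run the per-study and
#' pooled meta-analysis, pooled ROC per signature, a paired DeLong
#' comparison of the first two signatures, the random-gene-set resampling
#' null for the first dual-direction signature, and (optionally)
#' over-representation analysis of that signature against a gene-set
#' collection. Reports are written as TSV/JSON under `out_dir`, together
#' with a manifest recording the stages run, the seed, and input summaries.
#'
#' @param matrices named list of per-study `expr_matrix` objects (or paths
#'   to expression TSVs, read as log2 intensities).
#' @param meta a [sample_table()] data frame or path to a metadata TSV.
#' @param signatures named list of `gene_signature` objects (or paths to
#'   signature TSVs).
#' @param methods character vector along `signatures`: `"mean"` or
#'   `"updown-t"` per signature.
#' @param directions character vector along `signatures`: `"case-high"` or
#'   `"case-low"` per signature (ROC orientation; see [roc_curve()]).
#' @param out_dir output directory (created if needed).
#' @param seed integer seed driving the resampling stage.
#' @param n_iter resampling iterations (0 skips the null stage).
#' @param alpha significance level for the null stage.
#' @param gmt optional named list of gene sets (or a GMT path) for the
#'   enrichment stage; the universe is the cross-study gene intersection.
#' @param min_genes scoring guard, see [mean_target_score()].
#' @return invisibly, a list with all stage results (`scores`, `meta`,
#'   `roc`, `delong`, `null`, `enrichment`, `manifest`).
#' @export
run_full_analysis <- function(matrices, meta, signatures, methods,
                              directions, out_dir, seed = 1, n_iter = 200,
                              alpha = 0.05, gmt = NULL, min_genes = 10) {
  if (is.character(matrices))
    matrices <- stats::setNames(
      lapply(matrices, read_expression_matrix), names(matrices))
  if (is.character(meta)) meta <- read_sample_table(meta)
  if (is.character(signatures))
    signatures <- stats::setNames(lapply(signatures, read_signature),
                                  names(signatures))
  if (is.character(gmt) && length(gmt) == 1L) gmt <- read_gmt(gmt)
  nsig <- length(signatures)
  if (length(methods) != nsig || length(directions) != nsig)
    stop("signatures, methods and directions must have equal length")
  if (is.null(names(signatures)))
    names(signatures) <- vapply(signatures, `[[`, "", "name")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }
  stages <- character(0)
  write_json <- function(x, file)
    jsonlite::write_json(x, file.path(out_dir, file), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)

  ## stage 1: scoring ------------------------------------------------------
  scores <- stage("score", {
    out <- list()
    for (nm in names(signatures)) {
      sc <- score_studies(matrices, meta, signatures[[nm]],
                          method = methods[[match(nm, names(signatures))]],
                          min_genes = min_genes)
      utils::write.table(sc, file.path(out_dir, paste0("scores_", nm, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      out[[nm]] <- sc
    }
    out
  })
  stages <- c(stages, "score")

  ## stage 2: meta-analysis ------------------------------------------------
  meta_res <- stage("meta", {
    out <- list()
    for (nm in names(scores)) {
      ma <- meta_analyze(scores[[nm]])
      utils::write.table(ma$per_study,
                         file.path(out_dir, paste0("forest_", nm, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      write_json(unclass(ma$meta), paste0("meta_", nm, ".json"))
      out[[nm]] <- ma
    }
    out
  })
  stages <- c(stages, "meta")

  ## stage 3: pooled ROC ----------------------------------------------------
  roc_res <- stage("roc", {
    out <- list()
    for (nm in names(scores)) {
      sc <- scores[[nm]]
      rc <- roc_curve(sc$z_score, sc$group,
                      direction = directions[[match(nm, names(signatures))]])
      utils::write.table(
        data.frame(threshold = rc$thresholds, fpr = rc$fpr, tpr = rc$tpr),
        file.path(out_dir, paste0("roc_points_", nm, ".tsv")),
        sep = "\t", quote = FALSE, row.names = FALSE)
      out[[nm]] <- rc
    }
    write_json(lapply(out, function(r)
      list(auc = r$auc, direction = r$direction,
           n_case = r$n_case, n_control = r$n_control)), "roc.json")
    out
  })
  stages <- c(stages, "roc")

  ## stage 4: DeLong comparison of the first two signatures -----------------
  delong <- NULL
  if (nsig >= 2L) {
    delong <- stage("delong", {
      a <- scores[[1]]; b <- scores[[2]]
      common <- intersect(a$sample_id, b$sample_id)
      dl <- delong_paired(a$z_score[match(common, a$sample_id)],
                          b$z_score[match(common, b$sample_id)],
                          a$group[match(common, a$sample_id)],
                          direction_a = directions[[1]],
                          direction_b = directions[[2]])
      write_json(c(list(signature_1 = names(scores)[1],
                        signature_2 = names(scores)[2]), unclass(dl)),
                 "delong.json")
      dl
    })
    stages <- c(stages, "delong")
  }

  ## stage 5: resampling null ----------------------------------------------
  null_res <- NULL
  dual <- which(vapply(signatures, function(s) length(s$down) > 0, TRUE))
  if (n_iter > 0L && length(dual) >= 1L) {
    null_res <- stage("resample", {
      sig <- signatures[[dual[1]]]
      obs <- meta_res[[dual[1]]]$meta$fisher_p
      nd <- null_meta_distribution(matrices, meta,
                                   n_up = length(sig$up),
                                   n_down = length(sig$down),
                                   n_iter = n_iter, alpha = alpha,
                                   seed = seed, observed_fisher_p = obs,
                                   min_genes = min_genes)
      write_json(unclass(nd), "null.json")
      nd
    })
    stages <- c(stages, "resample")
  }

  ## stage 6: enrichment ----------------------------------------------------
  enr <- NULL
  if (!is.null(gmt) && length(dual) >= 1L) {
    enr <- stage("enrich", {
      sig <- signatures[[dual[1]]]
      universe <- Reduce(intersect, lapply(matrices, rownames))
      e_up <- enrich_collection(intersect(sig$up, universe), gmt, universe)
      e_dn <- enrich_collection(intersect(sig$down, universe), gmt, universe)
      utils::write.table(e_up, file.path(out_dir, "enrichment_up.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(e_dn, file.path(out_dir, "enrichment_down.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      robust <- robust_inverse_pairs(e_up, e_dn, alpha = alpha)
      utils::write.table(robust, file.path(out_dir, "robust_pairs.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      list(up = e_up, down = e_dn, robust = robust)
    })
    stages <- c(stages, "enrich")
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("metasig")),
    seed = seed,
    stages = stages,
    inputs = list(
      studies = lapply(matrices, function(m)
        list(n_genes = nrow(m), n_samples = ncol(m), scale = expr_scale(m))),
      n_samples = nrow(meta),
      signatures = lapply(signatures, function(s)
        list(n_up = length(s$up), n_down = length(s$down)))))
  write_json(manifest, "manifest.json")
  invisible(list(scores = scores, meta = meta_res, roc = roc_res,
                 delong = delong, null = null_res, enrichment = enr,
                 manifest = manifest))
}
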