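#' Configuration for the multi-study case/control cohort simulator
#'
#' The defaults emulate the structure of the biopsy compendium the scoring
#' and meta-analysis machinery targets: five independent case/control
#' cohorts totalling 82 cases and 82 controls, a 311-up / 290-down
#' signature, study-specific per-gene batch offsets, and a planted
#' "repression" effect in cases (up-targets shifted down by `effect_delta`
#' log2 units, down-targets shifted up). `platform = "gaussian_log"` draws
#' Gaussian log2 intensities (microarray-like); `"negative_binomial"` draws
#' NB counts (RNA-seq-like) around exponentiated means.
#'
#' @param n_studies number of studies.
#' @param n_case,n_control integer vectors (recycled to `n_studies`).
#' @param n_genes genes per matrix.
#' @param n_up,n_down planted signature sizes.
#' @param effect_delta mean case shift of signature genes, log2 units (>= 0).
#' @param direction `"repression"` (up-targets down in cases) or
#'   `"activation"` (mirrored signs).
#' @param batch_sd sd of study-level per-gene offsets.
#' @param noise_sd residual sd (gaussian platform).
#' @param platform `"gaussian_log"` or `"negative_binomial"`.
#' @param nb_dispersion NB dispersion (variance = mu + dispersion * mu^2).
#' @param seed master integer seed.
#' @return validated config list of class `"cohort_sim_config"`.
#' @export
cohort_sim_config <- function(n_studies = 5,
                              n_case = c(26, 16, 14, 14, 12),
                              n_control = c(24, 16, 14, 14, 14),
                              n_genes = 4000, n_up = 311, n_down = 290,
                              effect_delta = 1, direction = "repression",
                              batch_sd = 0.5, noise_sd = 0.5,
                              platform = c("gaussian_log", "negative_binomial"),
                              nb_dispersion = 0.1, seed = 1) {
  platform <- match.arg(platform)
  n_case <- rep_len(as.integer(n_case), n_studies)
  n_control <- rep_len(as.integer(n_control), n_studies)
  if (n_studies < 1L || any(n_case < 1L) || any(n_control < 1L))
    stop("study counts and group sizes must be positive")
  if (n_up + n_down >= n_genes)
    stop("signature sizes must be smaller than n_genes")
  if (effect_delta < 0 || batch_sd < 0 || noise_sd < 0 || nb_dispersion < 0)
    stop("effect_delta and sds must be non-negative")
  if (!direction %in% c("repression", "activation"))
    stop("direction must be 'repression' or 'activation'")
  structure(list(n_studies = n_studies, n_case = n_case,
                 n_control = n_control, n_genes = n_genes, n_up = n_up,
                 n_down = n_down, effect_delta = effect_delta,
                 direction = direction, batch_sd = batch_sd,
                 noise_sd = noise_sd, platform = platform,
                 nb_dispersion = nb_dispersion, seed = as.integer(seed)),
            class = "cohort_sim_config")
}

#' Simulate multi-study case/control cohorts with a planted signature
#'
#' Baseline per-gene means are Normal(7, 1) on the log2 scale; each study
#' adds its own Normal(0, `batch_sd`) per-gene offset; case samples of the
#' planted signature genes are shifted by `effect_delta` with signs set by
#' `direction`. The gaussian platform adds Normal(0, `noise_sd`) noise; the
#' negative-binomial platform exponentiates the (shifted) log2 means to
#' rates and draws NB counts. One master seed expands into per-study
#' substreams, so regenerating a single study is stable. The planted truth
#' is returned for recovery tests.
#'
#' @param cfg a [cohort_sim_config()].
#' @return list: `matrices` (named list of `expr_matrix`), `samples` (a
#'   [sample_table()] data frame), `signature` (the planted
#'   `gene_signature`), `config`.
#' @export
simulate_cohorts <- function(cfg = cohort_sim_config()) {
  stopifnot(inherits(cfg, "cohort_sim_config"))
  genes <- sprintf("g%05d", seq_len(cfg$n_genes))
  up <- genes[seq_len(cfg$n_up)]
  down <- genes[cfg$n_up + seq_len(cfg$n_down)]
  sgn <- if (cfg$direction == "repression") -1 else 1
  shift <- numeric(cfg$n_genes)
  shift[seq_len(cfg$n_up)] <- sgn * cfg$effect_delta
  shift[cfg$n_up + seq_len(cfg$n_down)] <- -sgn * cfg$effect_delta

  set.seed(cfg$seed)
  base_mu <- stats::rnorm(cfg$n_genes, mean = 7, sd = 1)
  study_seeds <- sample.int(.Machine$integer.max - 1L, cfg$n_studies)

  matrices <- list(); rows <- list()
  for (s in seq_len(cfg$n_studies)) {
    set.seed(study_seeds[s])
    study <- sprintf("study%d", s)
    nc <- cfg$n_case[s]; nn <- cfg$n_control[s]
    ids <- sprintf("%s_%s%02d", study,
                   rep(c("case", "ctrl"), c(nc, nn)),
                   c(seq_len(nc), seq_len(nn)))
    grp <- rep(c("case", "control"), c(nc, nn))
    offs <- stats::rnorm(cfg$n_genes, 0, cfg$batch_sd)
    mu <- matrix(base_mu + offs, cfg$n_genes, nc + nn)
    mu[, grp == "case"] <- mu[, grp == "case"] + shift
    if (cfg$platform == "gaussian_log") {
      vals <- mu + matrix(stats::rnorm(length(mu), 0, cfg$noise_sd),
                          nrow(mu), ncol(mu))
      scale <- "log2_intensity"
    } else {
      rate <- 2^mu
      vals <- matrix(stats::rnbinom(length(mu), mu = as.vector(rate),
                                    size = 1 / cfg$nb_dispersion),
                     nrow(mu), ncol(mu))
      vals <- vals * 1.0  # integer counts as numeric storage
      scale <- "counts"
    }
    dimnames(vals) <- list(genes, ids)
    matrices[[study]] <- expr_matrix(vals, scale)
    rows[[s]] <- data.frame(sample_id = ids, study_id = study, group = grp,
                            stringsAsFactors = FALSE)
  }
  list(matrices = matrices,
       samples = sample_table(do.call(rbind, rows)),
       signature = gene_signature("planted", up = up, down = down,
                                  provenance = "simulated ground truth"),
       config = cfg)
}

#' Configuration for the over-expression experiment simulator
#'
#' Emulates the design used to derive target-gene signatures: a control arm,
#' an over-expression arm shifting the true up targets by `+effect` and true
#' down targets by `-effect` (log2 units), and — with `dual_construct =
#' TRUE` — a dominant-negative arm with mirrored shifts, all in
#' `n_replicates` replicates with Gaussian noise.
#'
#' @param n_genes genes.
#' @param n_true_up,n_true_down planted target counts
#'   (`n_true_up + n_true_down < n_genes`).
#' @param n_replicates replicates per arm (default 3, a triplicate design).
#' @param effect log2 shift of true targets in the over-expression arm.
#' @param noise_sd residual sd.
#' @param dual_construct add the dominant-negative arm.
#' @param seed integer seed.
#' @return validated config list of class `"oe_sim_config"`.
#' @export
oe_sim_config <- function(n_genes = 2000, n_true_up = 30, n_true_down = 30,
                          n_replicates = 3, effect = 2, noise_sd = 0.3,
                          dual_construct = TRUE, seed = 1) {
  if (n_true_up + n_true_down >= n_genes)
    stop("n_true_up + n_true_down must be < n_genes")
  if (n_replicates < 2L) stop("need >= 2 replicates per arm")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  structure(list(n_genes = n_genes, n_true_up = n_true_up,
                 n_true_down = n_true_down, n_replicates = n_replicates,
                 effect = effect, noise_sd = noise_sd,
                 dual_construct = isTRUE(dual_construct),
                 seed = as.integer(seed)),
            class = "oe_sim_config")
}

#' Simulate a (dual-construct) over-expression experiment
#'
#' @param cfg an [oe_sim_config()].
#' @return list: `matrix` (an `expr_matrix`, log2 intensities, arms in
#'   columns), `arms` (character vector along columns: `"control"`,
#'   `"overexpression"`, and `"dominant_negative"` when simulated),
#'   `true_up`, `true_down`, `config`.
#' @export
simulate_overexpression <- function(cfg = oe_sim_config()) {
  stopifnot(inherits(cfg, "oe_sim_config"))
  set.seed(cfg$seed)
  genes <- sprintf("g%05d", seq_len(cfg$n_genes))
  true_up <- genes[seq_len(cfg$n_true_up)]
  true_down <- genes[cfg$n_true_up + seq_len(cfg$n_true_down)]
  shift <- numeric(cfg$n_genes)
  shift[seq_len(cfg$n_true_up)] <- cfg$effect
  shift[cfg$n_true_up + seq_len(cfg$n_true_down)] <- -cfg$effect
  base_mu <- stats::rnorm(cfg$n_genes, 7, 1)
  arms <- c("control", "overexpression",
            if (cfg$dual_construct) "dominant_negative")
  arm_shift <- c(control = 0, overexpression = 1, dominant_negative = -1)
  cols <- list(); labels <- character(0)
  for (arm in arms) {
    mu <- base_mu + arm_shift[[arm]] * shift
    reps <- matrix(stats::rnorm(cfg$n_genes * cfg$n_replicates, mu,
                                cfg$noise_sd),
                   cfg$n_genes, cfg$n_replicates)
    colnames(reps) <- sprintf("%s_r%d", arm, seq_len(cfg$n_replicates))
    cols[[arm]] <- reps
    labels <- c(labels, rep(arm, cfg$n_replicates))
  }
  vals <- do.call(cbind, cols)
  rownames(vals) <- genes
  list(matrix = expr_matrix(vals, "log2_intensity"), arms = labels,
       true_up = true_up, true_down = true_down, config = cfg)
}

#' Derive a dual-construct signature from a simulated experiment
#'
#' Convenience wrapper: runs [two_group_de()] for the over-expression arm vs
#' control and (if present) for the dominant-negative arm vs control, then
#' applies [select_targets_dual()] — or [select_targets_single()] when no
#' dominant-negative arm was simulated.
#'
#' @param sim result of [simulate_overexpression()].
#' @param ... thresholds passed to the selection rule.
#' @return a `gene_signature`.
#' @export
derive_from_simulation <- function(sim, ...) {
  m <- sim$matrix; arms <- sim$arms
  keep_oe <- arms %in% c("control", "overexpression")
  de_oe <- two_group_de(as_expr(unclass(m)[, keep_oe, drop = FALSE],
                                expr_scale(m)),
                        groups = arms[keep_oe],
                        treated = "overexpression", control = "control")
  if (!sim$config$dual_construct)
    return(select_targets_single(de_oe, ...))
  keep_dn <- arms %in% c("control", "dominant_negative")
  de_dn <- two_group_de(as_expr(unclass(m)[, keep_dn, drop = FALSE],
                                expr_scale(m)),
                        groups = arms[keep_dn],
                        treated = "dominant_negative", control = "control")
  select_targets_dual(de_oe, de_dn, ...)
}

#' Synthetic stand-ins for the published target-gene signature files
#'
#' Constructs four synthetic gene signatures whose *sizes* and *pairwise
#' overlaps* match the published target-gene lists the pipeline consumes:
#' three activated-target DUX4-style sets of 114, 212 and 165 genes with
#' pairwise overlaps 29 (set1 vs set2), 45 (set1 vs set3) and 28 (set3 vs
#' set2), and a dual-direction PAX7-style signature of 311 up and 290 down
#' genes. Gene identifiers are synthetic placeholders (`siggene_*`,
#' `paxgene_*`): the real membership is supplementary *data*, not code, and
#' is not reproduced here — these stand-ins exercise file round-trips and
#' size/overlap bookkeeping only.
#'
#' @return named list of `gene_signature` objects:
#'   `dux4_rnaseq_114`, `dux4_rnaseq_212`, `dux4_array_165`, `pax7_311_290`.
#' @export
synthetic_published_signatures <- function() {
  pool <- function(prefix, n) sprintf("%s_%04d", prefix, seq_len(n))
  # overlap blocks: triple (size 20, chosen; not a published number),
  # pairwise-only blocks sized so total pairwise overlaps are 29 / 45 / 28
  blocks <- list(T = pool("siggene_t", 20),
                 AB = pool("siggene_ab", 9),   # 114-set with 212-set: 20+9 = 29
                 AC = pool("siggene_ac", 25),  # 114-set with 165-set: 20+25 = 45
                 CB = pool("siggene_cb", 8),   # 165-set with 212-set: 20+8 = 28
                 A = pool("siggene_a", 60), B = pool("siggene_b", 175),
                 C = pool("siggene_c", 112))
  a <- c(blocks$T, blocks$AB, blocks$AC, blocks$A)   # 114
  b <- c(blocks$T, blocks$AB, blocks$CB, blocks$B)   # 212
  c3 <- c(blocks$T, blocks$AC, blocks$CB, blocks$C)  # 165
  prov <- "synthetic stand-in: sizes/overlaps match the published lists"
  list(dux4_rnaseq_114 = gene_signature("dux4_rnaseq_114", up = a, provenance = prov),
       dux4_rnaseq_212 = gene_signature("dux4_rnaseq_212", up = b, provenance = prov),
       dux4_array_165 = gene_signature("dux4_array_165", up = c3, provenance = prov),
       pax7_311_290 = gene_signature("pax7_311_290",
                                     up = pool("paxgene_up", 311),
                                     down = pool("paxgene_dn", 290),
                                     provenance = prov))
}
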