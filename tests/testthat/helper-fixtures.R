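# small in-code fixtures shared across test files

make_em <- function(vals, scale = "log2_intensity",
                    genes = sprintf("g%d", seq_len(nrow(vals))),
                    samples = sprintf("s%d", seq_len(ncol(vals)))) {
  dimnames(vals) <- list(genes, samples)
  expr_matrix(vals, scale)
}

# tiny two-study cohort with a planted repression effect, fast to score
tiny_cohort <- function(effect_delta = 1, seed = 42, n_genes = 300,
                        n_up = 25, n_down = 25, n_studies = 2,
                        n_case = 8, n_control = 8) {
  simulate_cohorts(cohort_sim_config(
    n_studies = n_studies, n_case = n_case, n_control = n_control,
    n_genes = n_genes, n_up = n_up, n_down = n_down,
    effect_delta = effect_delta, seed = seed))
}

# brute-force two-sided Mann-Whitney p by enumerating all labelings
enumerate_mwu_p <- function(x, y) {
  n1 <- length(x); pool <- c(x, y)
  u_of <- function(idx) sum(rank(pool)[idx]) - n1 * (n1 + 1) / 2
  obs <- u_of(seq_len(n1))
  us <- apply(utils::combn(length(pool), n1), 2, u_of)
  min(1, 2 * min(mean(us <= obs), mean(us >= obs)))
}

# explicit min-over-suffix Benjamini-Hochberg
brute_bh <- function(p) {
  n <- length(p); o <- order(p); q <- numeric(n)
  ps <- p[o]
  for (i in seq_len(n)) q[i] <- min(ps[i:n] * n / (i:n), 1)
  res <- numeric(n)
  res[o] <- q
  res
}

# brute-force AUC by pair counting with half ties
brute_auc <- function(case, control) {
  s <- 0
  for (x in case) for (y in control) s <- s + (x > y) + 0.5 * (x == y)
  s / (length(case) * length(control))
}
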