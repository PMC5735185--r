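---
title: "Signature biomarkers across studies: scoring, meta-analysis and nulls"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Signature biomarkers across studies: scoring, meta-analysis and nulls}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metasig)
```

# The model

A *gene signature* here is a pair of disjoint gene sets: targets induced by
a transcription factor (the up set) and targets it suppresses (the down
set, possibly empty). Two single-sample scores turn a signature into a
per-sample scalar:

* **Mean score** — the arithmetic mean of the up-target expression in the
  sample. Appropriate for strong activators whose induced targets carry
  all of the usable signal (the down set only adds noise).
* **Up-vs-down t score** — the two-sample Welch t statistic comparing the
  up-target values against the down-target values *within the sample*.
  Appropriate for factors that modulate transcription in both directions:
  the contrast doubles the signal and cancels sample-wide shifts, since
  any additive offset common to all genes of a sample drops out of the
  difference of means.

Scores from different cohorts are not comparable — platforms differ in
dynamic range and preprocessing — so scores are z-normalised *within each
study* (all samples together, n−1 denominator) before any pooled analysis.
For matched designs (patient/control cell-line pairs), passing the pairing
identifier as the grouping variable gives per-pair z-scores with no extra
code path.

Cross-study inference then has three prongs:

1. per-study two-sided Mann–Whitney tests of case vs control scores,
   with the difference of mean z-scores ± its Welch-type standard error
   as the forest-plot effect;
2. DerSimonian–Laird random-effects pooling of those effects
   ($\tau^2$ by the method of moments from Cochran's $Q$) and Fisher's
   combined test $-2\sum_k \log p_k \sim \chi^2_{2k}$ over the per-study
   Wilcoxon p-values;
3. pooled ROC analysis of the concatenated z-scores, with DeLong's test
   for comparing two signatures scored on the same samples.

Finally, a significance statement about one particular signature is only
meaningful against matched-size random gene sets: the resampling null
re-runs the entire scoring + meta-analysis pipeline on randomly drawn
up/down pairs of the same sizes and reports where the observed combined p
falls in that distribution.

# Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `fc_thresh`, `fdr_thresh` (single rule) | 2, 0.05 | strict cuts on log2 FC and BH FDR for activated targets |
| `fc_thresh`, `p_thresh` (dual rule) | 1, 0.05 | per-arm cuts; p unadjusted, as the rule is a conjunction of two tests |
| `dn_rule` | `"strict-sign"` | see below |
| `min_genes` | 10 | minimum matched genes per signature set before scoring is allowed |
| `variance` (t score) | `"welch"` | Welch vs pooled within-sample t |
| `direction` (ROC) | — | explicit per signature; never auto-detected |
| `n_iter` (null) | 1000 | random signatures drawn; empirical p floor is 1/(n_iter+1) |

Fold-change thresholds are on the log2 scale, the universal convention for
these platforms.

# Design choices

**Dominant-negative rule.** The dual-construct selection is usually stated
as "log FC > 1 under over-expression and log FC < 1 under the dominant
negative". Read literally, the second clause admits genes the dominant
negative barely moves (fold changes in (−1, 1)); the verbal definition
("suppressed by the dominant negative") implies crossing −1. Both readings
are implemented: `dn_rule = "strict-sign"` (default) requires the sign to
flip past the threshold, `"literal"` applies the inequality as printed.
This is an ambiguity we document rather than resolve.

**DE engine.** Signature derivation uses this package's own two-group
engine: Welch t by default, or a moderated t in which pooled gene
variances are shrunk toward an empirical-Bayes prior (moment-matched
scaled-F model, with the prior degrees of freedom added to the residual
ones). The engine is deliberately simple — signature membership at the
margins is engine-dependent, which is why published signature lists should
be consumed as data files while the derivation code is validated on
planted-truth simulations, where the package recovers all planted targets
with zero false positives at the triplicate design.

**Score conventions.** The mean score is computed on the matrix's log
scale as given (no per-gene standardisation first): that is the simplest
reading of "average expression", and the within-study z-normalisation that
follows removes the study-level location/scale anyway. The t score uses
Welch variances because up and down sets differ in size and spread; a
pooled option exists for sensitivity analysis. z-normalisation uses *all*
samples of a study, not controls only — pooled ROC needs identically
distributed predictors in both groups.

**Meta-analysis conventions.** DerSimonian–Laird is the classic
random-effects estimator for this design; REML is out of scope. Fisher's
combined test consumes the per-study Wilcoxon p-values (matching the
per-study significance tests); `p_source = "effect"` switches to
normal-theory p-values of the effect estimates. The Wilcoxon exact branch
(total n ≤ 12, no ties) uses the doubling rule
`p = min(1, 2 min(P(U≤u), P(U≥u)))`; larger or tied samples use the
normal approximation with continuity correction and tie-corrected
variance. Across an exhaustive sweep of tie-free inputs with 6 ≤ n ≤ 12
the two branches agree within 0.05 (worst case at the smallest group
sizes); the suite pins this bound.

**ROC direction.** Whether a high or a low score indicates case status is
biology, not statistics: repression signatures discriminate by *low*
scores in cases. The orientation is therefore an explicit argument
(`"case-high"`/`"case-low"`); auto-detecting it from the data would
inflate every AUC above 0.5 by construction. Ties count one half in both
the AUC and the DeLong placement values.

**Resampling null.** Random up/down sets are drawn disjoint, without
replacement, from the intersection of genes measured in every study, and
the true signature genes are *not* excluded (the plain reading of "random
gene sets of equivalent size"). The empirical p uses the +1 correction so
it can never be zero — with 1000 draws the strongest statement available
is "less than 1/1000". Iteration seeds are expanded from one master seed,
so the whole distribution is reproducible and order-independent.

**Enrichment.** Over-representation uses the hypergeometric upper tail
with an explicit universe — the genes measured on the platform the
signature came from. Defaulting the universe to the union of the GMT
collection is a classic way to manufacture enrichment, so the argument is
required. The robust inverse-enrichment criterion gates on nominal
p < 0.05 by default (with a q-value mode), and requires the activated and
repressed targets to hit *opposite* `_UP`/`_DN` halves of the same base
set name.

# Numerical and degenerate-input behaviour

* Quantile normalisation resolves ties by assigning the mean of the
  reference values over the occupied ranks. With ties present the
  transform is not exactly idempotent (a tied block collapses to its
  block mean, which perturbs the shared reference); on tie-free columns
  idempotence and cross-column identity of sorted values are exact.
* Size factors use the median of ratios to the per-gene geometric mean
  over samples; genes with any zero count drop out of the reference, and
  a matrix where every gene has a zero is an error. Counts become
  `log2(x / sf + 1)`.
* Zero-variance cases are never silent: a gene with zero variance in both
  groups gets p ∈ {0, 1} with a warning; a sample whose up- and
  down-target values are all constant scores 0 with a warning; a study
  with one sample or zero score variance refuses to z-normalise.
* A Fisher input p of exactly 0 yields combined p 0 with a warning rather
  than NaN.
* `min_genes = 10` guards every scoring call: signatures that barely
  overlap the measured genes fail loudly, never degrade into means of two
  or three genes.

# What the simulators emulate — and what they do not

`simulate_cohorts()` mirrors the structure of a typical biopsy
compendium: five case/control studies totalling 82 cases and 82 controls
(per-study splits 26/24, 16/16, 14/14, 14/14, 12/14 — a design choice
matching the published totals, since per-study counts live in
supplementary material), baseline log2 means Normal(7, 1), per-study
per-gene batch offsets Normal(0, 0.5), residual noise sd 0.5, and a
311-up/290-down signature shifted by `effect_delta` (default 1) in cases,
down-targets mirrored. The negative-binomial platform (dispersion 0.1)
emulates RNA-seq counts, which flow through size-factor normalisation
into the same log-scale interface. `simulate_overexpression()` mirrors
the triplicate over-expression / dominant-negative / control design with
planted true targets (30 + 30, effect 2, noise 0.3 by default).

The simulators deliberately omit gene–gene correlation, probe-level
physics, sequencing-depth gradients and biological heterogeneity beyond
the planted shift. Two consequences to keep in mind. First, averaging
hundreds of independent genes shrinks score noise like $1/\sqrt{m}$, so
planted effects separate cases from controls far more cleanly than real
cohorts do — a pooled AUC of 1.0 at `effect_delta = 1` says the pipeline
is correct, not that real biopsies are that easy. Second, calibration
results (null uniformity, false-positive fractions near $\alpha$) do
carry over, because they hold under the global null where the omissions
matter least. Passing recovery tests therefore demonstrates correctness
of the machinery, not field performance.

Problem sizes in the test suite are scaled to keep the full run fast
(cohorts of a few hundred to 4000 genes, nulls of 150–400 iterations,
100-replicate power sweeps); all are stated in the tests themselves and
none were tuned against the assertions they feed.

# Known limitations

* The DE engine is a stand-in: it will not reproduce published signature
  memberships derived with other machinery at the threshold margins.
* DeLong's test here is the paired variant only; comparing AUCs across
  disjoint sample sets needs the unpaired form, which is out of scope.
* The resampling null matches set *sizes* only, not expression level or
  variance profiles of the true signature genes.
* Meta-analysis assumes independent studies; overlapping cohorts would
  invalidate Fisher's combination.

# A minimal end-to-end run

```{r example, eval = FALSE}
sim <- simulate_cohorts(cohort_sim_config(
  n_studies = 3, n_case = 16, n_control = 16, n_genes = 2000,
  n_up = 100, n_down = 100, effect_delta = 0.1, seed = 20))
rand <- random_signature(rownames(sim$matrices$study1), 100, 100, seed = 1)

res <- run_full_analysis(
  matrices = sim$matrices, meta = sim$samples,
  signatures = list(true = sim$signature, random = rand),
  methods = c("updown-t", "updown-t"),
  directions = c("case-low", "case-low"),
  out_dir = tempfile("run"), seed = 7, n_iter = 200)

res$meta$true$meta     # pooled effect, tau2, Fisher's combined p
res$roc$true$auc       # pooled AUC of the planted signature
res$delong             # paired comparison against the random signature
res$null$empirical_p   # where the observed biomarker falls in the null
```
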