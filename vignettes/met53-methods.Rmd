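---
title: "Methods: signature scoring, co-occurrence stratification and the synthetic study conditions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: signature scoring, co-occurrence stratification and the synthetic study conditions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(met53)
```

## The model and its assumptions

The package analyses the co-occurrence of two alterations in an HCC
cohort: a transcriptional *activation state* defined by a gene-set
signature, and a *mutation state* defined by variant calls in a single
gene (TP53 in the motivating application). The analysis chain is:

1. **Per-gene standardization.** Every gene is z-transformed using the
   mean and sample SD of a reference population. The z-transform is an
   affine map per gene, so within-gene sample rankings are preserved
   regardless of the reference. Genes with zero reference variance carry
   no information on that scale and are dropped (and reported).
2. **Signature score.** The per-sample score is the unweighted mean of
   the member genes' z-values: every gene carries weight 1, and the
   score is dimensionless (units of reference SDs). The implicit
   assumption is that the signature acts coherently — all members move
   up together under activation — which is what the score's mean
   structure rewards.
3. **Activation threshold.** τ = mean(ST scores) + k·sd(ST scores) with
   k = 1.5. Anchoring τ to the surrounding-tissue (ST) distribution
   makes the call a *departure from non-tumor tissue*, not a split of
   the tumor distribution; if scores are approximately Gaussian in ST,
   k = 1.5 corresponds to an expected false-activation rate of
   `pnorm(-1.5)` ≈ 6.7%. The call is strict: a score exactly at τ is
   "low" ("more than" the threshold).
4. **Stratification and survival.** Mutant status crosses activation
   class into four strata; the headline survival contrast is the
   double-altered stratum against the pooled remaining three, matching
   the question "is the co-occurring subset worse off than everyone
   else?". Pairwise stratum contrasts are available behind
   `contrast = "pairwise"` and are deliberately reported unadjusted.

The Kaplan–Meier estimator and the log-rank (Mantel–Cox) test are
implemented from first principles rather than delegated, because they
are part of the package's analytic surface and must be auditable down
to the risk-set accounting. The test suite cross-checks both against
the survival package to 1e-9.

## Tunable parameters

| Parameter | Default | Meaning and rationale |
|---|---|---|
| `k` | 1.5 | multiplier on the ST score SD; the field's convention for this signature call |
| `reference` | `"all"` | standardization population; the heatmap-style analysis standardizes the full matrix. `"st"`/`"hcc"` available; the choice shifts all scores and τ by the same per-gene affine map, so the *ordering* of samples is unchanged |
| `ddof` | 1 | sample SD throughout; the conventional estimator. Surfaced as a knob because the definition only says "SD" |
| `null_definition` | truncating, splice, deletion_null | which variant classes count as TP53-*null*. The null subset is not crisply defined upstream, so it is an explicit, logged parameter |
| `min_genes` | all members | scoring with missing signature genes is a hard error by default: an 18-gene set is small enough that silent loss changes the statistic. Lower `min_genes` to score the present subset; the missing symbols are stored |
| DEG filter | FC > 1.5, p_adj < 0.05 | both strict inequalities; fold change is linear (log2 inputs are converted on read). An optional raw-p gate exists but is off: the adjusted-p gate alone is the defensible default when the upstream convention is ambiguous |
| ORA universe | genes in the statistic table | the universe choice changes every enrichment p, so it is explicit and recorded in the run manifest |
| IC50 | relative | the 4PL inflection concentration, the standard "IC50" of curve-fitting software; the absolute-50% crossing is exposed as `ic50_absolute` |

Standardize-before-or-after-subsetting is a non-question under the
defaults: the z-transform is per-gene, so subsetting to the signature
genes before or after standardizing gives identical member z-values as
long as the reference population is unchanged. Both orderings are
therefore available trivially (standardize the full matrix, or a
subsetted one) and documented here once.

## What the synthetic cohort emulates

`simulate_cohort()` generates the study conditions the analysis assumes,
with defaults fixed once:

* **360 HCC + 50 ST samples**, the dimensions of the human cohort the
  analysis targets; **111/360 mutants**.
* **Marginal activated fraction 215/360** and **co-occurrence odds
  ratio 2.0**: the published stratum counts (79/111 mutant-high,
  136/249 wild-type-high) imply a marginal of 215/360 and an odds ratio
  of (79·113)/(32·136) ≈ 2.05; the generator's round default of 2.0
  reproduces those row proportions to within sampling noise. Activation
  is sampled conditionally on mutant status with probabilities solved
  from (marginal, OR) by `cooccurrence_probs()` — a one-dimensional
  root-find on P(activated | wild-type). With this parameterisation any
  OR > 0 is feasible for marginals strictly inside (0, 1).
* **Signature shift 2.0 reference SDs** in planted-activated tumors over
  an 18-gene signature plus 200 Gaussian background genes (per-gene
  means drawn once, unit SD). Two SDs is a strong but realistic bulk
  expression effect and places the planted classes on either side of the
  k = 1.5 threshold without making the call trivial (planted-label
  recovery is ≈ 96%, not 100%).
* **Survival**: exponential event times with baseline hazard
  log(2)/60 per month (median overall survival 60 months, a realistic
  resected-HCC figure), multiplied by 2.5 in double-altered samples
  only; independent exponential censoring at rate log(2)/40, giving
  roughly 60% censoring at baseline. ST rows carry `os_time = 0`,
  `os_event = 0` — tissue samples have no follow-up and survival code
  uses HCC rows only.
* **Reproducibility**: one global seed expands into per-component child
  seeds (`seed + i·1000003 mod 2^31−1`, components: gene means,
  mutations, activation, expression noise, survival), so each
  sub-generator is independently reproducible and the whole generator is
  a pure function of its config.

`simulate_deg_counts()` confines count data to the DEG module:
negative-binomial counts (Poisson at dispersion 0) with a planted
upregulated fraction. The emitted statistic table carries an *estimated*
linear fold change and a Welch-t p-value computed on the
log2(count + 0.5) scale — the planted labels and true fold changes live
only in a separate truth table, so the analyst-facing table never leaks
truth. `simulate_dose_response()` draws OD values from a 4PL curve
scaled to a vehicle OD of 0.8 with Gaussian noise in viability points.

**What the generators do not emulate** — and hence what passing tests do
not show about real data: library-size and batch artifacts, gene–gene
correlation within and outside the signature, copy-number structure,
non-proportional hazards, informative censoring, and mutation-call
error. The synthetic recovery results certify the *pipeline's
arithmetic and calibration*, not robustness to those real-data features.

## Numerical choices

* **4PL fitting** uses Levenberg–Marquardt least squares on log10
  concentration with a deterministic start (top = max v, bottom = min v,
  hill = 1, IC50 = geometric median concentration) and a fixed restart
  grid over hill ∈ {0.5, 2, −1}; the best-deviance solution is polished
  by a second pass from its own optimum. Non-convergence and flat
  (bottom ≈ top) responses are *flags on the result*, never exceptions,
  so plate-screening loops do not abort. Vehicle wells anchor the
  normalization but are excluded from the fit (c = 0 has no log
  concentration). If the optimizer lands in the mirrored
  parameterisation (bottom > top), it is folded back by swapping the
  asymptotes and negating the hill slope — an exact identity of the
  model.
* **Log-rank ties**: events precede censoring at tied times (both
  remain in the risk set at that time), the standard convention. With
  more than two groups the statistic is the quadratic form of the
  observed-minus-expected vector against its hypergeometric covariance
  (one group dropped; pseudo-inverse fallback if the covariance is
  singular), with groups − 1 degrees of freedom.
* **Crosstab odds ratio**: Haldane's 0.5-per-cell correction only when a
  zero cell occurs, and then flagged on the result.
* **Degenerate score comparisons**: when both groups have zero variance
  the t-based methods refuse and direct the caller to the rank test.
* **Missing expression values are errors**, never imputed — downstream
  standardization must not guess.

## Problem sizes in the test suite

The suite exercises: 200 random matrices (≤ 10×10) against a loop-based
scoring oracle at 1e-12; exhaustive hypergeometric enumeration for
universes ≤ 15; a 10,000-permutation log-rank null on a 20-sample
instance; 400 null cohorts (hazard multiplier 1) for type-I calibration
at α = 0.05; 100 default cohorts for end-to-end recovery; and 9
noise-free plus 100 noisy 4PL plates. These sizes keep the full suite
around half a minute while leaving every Monte-Carlo check with
interpretable error bars.

One caveat surfaced by the suite and kept visible rather than papered
over: on 20-sample survival instances the chi-square approximation to
the exact permutation null of the log-rank statistic carries a
systematic bias of roughly 0.005–0.03 in the p-value (the asymptotic p
is slightly anti-conservative there). The implementation is exact in
its arithmetic — it matches independent cross-checks to 1e-9 — and the
approximation is well calibrated at the cohort sizes the analysis
actually uses (the 400-replicate null-cohort experiment at n = 360
rejects at 4–6%). For very small groups, a permutation p-value is the
appropriate tool.

## Known limitations

* The activation call is a hard threshold on a mean score; borderline
  samples get no uncertainty measure. A probabilistic call (e.g. mixture
  modelling) is out of scope.
* The DEG module consumes per-gene statistic tables; it does not fit
  count models itself, so its results inherit whatever upstream fitter
  produced the tables.
* Ortholog mapping without a table is a heuristic (uppercase plus a
  short exception list) intended for synthetic and quick-look use;
  serious cross-species work should supply a curated mapping table.
* Survival analysis stops at KM + log-rank by design: no Cox models,
  hazard-ratio confidence intervals or competing risks.
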