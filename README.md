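# met53

Co-occurrence analysis of c-MET transcriptional activation and *TP53*
mutation in hepatocellular carcinoma (HCC) cohorts, with the surrounding
preclinical quantitative analyses. The package is aimed at computational
biologists who want the whole chain — signature scoring, activation
calling, mutation stratification, survival comparison, cross-species DEG
overlap, IC50 fitting and xenograft growth analysis — as tested, reusable
R functions that run end to end on synthetic cohorts without any external
downloads.

## The statistics at the core

**Signature score and activation call.** Given a gene × sample expression
matrix, each gene *g* is standardized against a reference population *R*:

    z_gs = (x_gs − mean_R(x_g)) / sd_R(x_g)        (sample SD, ddof 1)

The per-sample score is the unweighted mean of the z-values over the
members of an activation gene set (an 18-gene c-MET signature in the
motivating application; every gene has weight 1). The activation
threshold is referenced to the surrounding-tissue (ST) samples:

    τ = mean(score_ST) + k · sd(score_ST),  k = 1.5 by default

and a tumor is called *c-MET high* iff its score strictly exceeds τ.

**Stratification and survival.** HCC samples are cross-classified by
*TP53* status (mutant iff ≥ 1 record of any variant class; "null" is a
parametric subset, by default truncating/splice/deletion) and activation
class, giving the four strata `mut_high`, `mut_low`, `wt_high`,
`wt_low`, a 2×2 crosstab with odds ratio, Kaplan–Meier curves per
stratum, and a log-rank (Mantel–Cox) test of the double-altered stratum
against the pooled rest. KM and log-rank are implemented from first
principles (product-limit estimator; hypergeometric expected counts and
covariance at each distinct event time) and are cross-checked against
the survival package in the test suite.

**DEG overlap and enrichment.** DEG tables (gene, fold change, p) are
filtered at fold change > 1.5 and BH-adjusted p < 0.05 (both strict),
mouse symbols are mapped to human (lookup table, or uppercase rule with
an exception list), overlaps are exact set algebra, and
over-representation of gene-set categories uses the upper-tail
hypergeometric test with BH adjustment across categories.

**Dose response and growth.** Crystal-violet OD readings are normalized
to percent viability against the vehicle-well mean; the 4PL model

    v(c) = bottom + (top − bottom) / (1 + (c / IC50)^hill)

is least-squares fitted on log10 concentration (relative IC50 = the
inflection concentration; the absolute-50% crossing is a derived field).
Caliper tumor volumes use V = A·B²/2 with A ≥ B, and endpoint group
comparisons use Student/Welch t or Mann–Whitney tests.

## Worked example

```r
library(met53)

sim <- simulate_cohort(cohort_sim_config(seed = 7))
res <- met_cooccurrence(sim$expression, sim$clinical, sim$mutations,
                        sim$gene_set)
print(res)
#> c-MET / TP53 co-occurrence analysis
#>   360 HCC samples classified (tau = -0.4719, k = 1.5, n_ST = 50)
#>   c-MET high: 71.2% of mutant (79/111), 55.8% of wild-type (139/249); OR = 1.95
#>   score, mutant vs wild-type (student): p = 0.00332
#>   log-rank, double-altered vs rest: chi-square = 39.316, p = 3.6e-10
```

Reading the output: of the 111 *TP53*-mutant tumors in this simulated
cohort, 71.2% score above the ST-referenced threshold τ = −0.47, against
55.8% of wild-type tumors (odds ratio 1.95), the signature score is
significantly higher in mutant tumors, and the double-altered stratum
has markedly worse overall survival than everyone else.

```r
dr <- normalize_viability(simulate_dose_response(ic50 = 16, noise_sd = 5,
                                                 seed = 7))
fit <- fit_4pl(dr$concentration, dr$viability)
print(fit)
#> Four-parameter logistic dose-response fit
#>   bottom = 1.888%, top = 95.42%, hill = 1.061, IC50 = 16.9768
#>   RSS = 685.5, converged: TRUE
```

A plate planted at IC50 = 16 µM with 5-point viability noise is
recovered at 16.98 µM. `coef()`, `predict()`, `residuals()`, `plot()`
and `simulate()` methods are available on the fit object.

File-driven runs with a manifest (checksums, warnings, timing) are
available through `run_cooccurrence()` / `run_overlap()` and the thin
CLI wrapper in `inst/scripts/met53`.

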