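# Seeded generators for synthetic cohorts, RNA-seq-like count tables and
# dose-response plates with the statistical structure the analysis assumes,
# so every stage is testable end to end without downloads.
#
# One global seed expands to per-component child seeds through a fixed
# scheme (seed + i * 1000003, modulo 2^31 - 1), so the expression,
# mutation, activation and survival draws are independently reproducible.

child_seed <- function(seed, i) {
  as.integer((as.numeric(seed) + i * 1000003) %% 2147483647)
}

#' Synthetic cohort configuration
#'
#' Defaults mirror the dimensions of the human cohort the analysis targets:
#' 360 HCC plus 50 surrounding-tissue (ST) samples, a 111/360 TP53-mutant
#' fraction, an 18-gene activation signature shifted by 2 reference SDs in
#' planted-activated tumors, a marginal activated fraction of 215/360 with
#' a co-occurrence odds ratio of 2 between mutation and activation, and
#' exponential survival with a 2.5-fold hazard in double-altered samples.
#'
#' @param n_hcc,n_st Sample counts (tumor / surrounding tissue).
#' @param mutant_fraction Fraction of HCC samples carrying a TP53 mutation.
#' @param n_signature_genes Number of signature genes.
#' @param signature_shift Expression shift of signature genes in
#'   planted-activated tumors, in units of the per-gene reference SD.
#' @param cooccurrence_or Odds ratio between mutant status and planted
#'   activation (> 0).
#' @param activated_fraction Marginal fraction of HCC samples with planted
#'   activation.
#' @param n_background_genes Number of non-signature background genes.
#' @param baseline_hazard Exponential event hazard per time unit (months).
#' @param hazard_multiplier Hazard multiplier for double-altered
#'   (mutant AND activated) samples.
#' @param censoring_rate Exponential censoring hazard.
#' @param seed Integer seed; the generator is a pure function of its
#'   configuration.
#' @return Object of class `cohort_sim_config`.
#' @export
cohort_sim_config <- function(n_hcc = 360, n_st = 50,
                              mutant_fraction = 111 / 360,
                              n_signature_genes = 18,
                              signature_shift = 2.0,
                              cooccurrence_or = 2.0,
                              activated_fraction = 215 / 360,
                              n_background_genes = 200,
                              baseline_hazard = log(2) / 60,
                              hazard_multiplier = 2.5,
                              censoring_rate = log(2) / 40,
                              seed = 1) {
  stopifnot(n_hcc >= 1, n_st >= 2, n_signature_genes >= 1,
            n_background_genes >= 1, baseline_hazard > 0,
            hazard_multiplier > 0, censoring_rate >= 0)
  if (mutant_fraction < 0 || mutant_fraction > 1)
    stop("mutant_fraction must lie in [0, 1]", call. = FALSE)
  if (activated_fraction < 0 || activated_fraction > 1)
    stop("activated_fraction must lie in [0, 1]", call. = FALSE)
  if (cooccurrence_or <= 0)
    stop("cooccurrence_or must be > 0", call. = FALSE)
  structure(list(n_hcc = n_hcc, n_st = n_st,
                 mutant_fraction = mutant_fraction,
                 n_signature_genes = n_signature_genes,
                 signature_shift = signature_shift,
                 cooccurrence_or = cooccurrence_or,
                 activated_fraction = activated_fraction,
                 n_background_genes = n_background_genes,
                 baseline_hazard = baseline_hazard,
                 hazard_multiplier = hazard_multiplier,
                 censoring_rate = censoring_rate,
                 seed = as.integer(seed)),
            class = "cohort_sim_config")
}

#' Conditional activation probabilities from marginal fraction and odds ratio
#'
#' Solves P(activated | wild-type) = p0 and P(activated | mutant) = p1 such
#' that odds(p1) = or * odds(p0) and the mixture reproduces the requested
#' marginal activated fraction. For interior marginals (strictly between 0
#' and 1) a solution exists for every or > 0; boundary marginals are
#' rejected with the feasible range.
#'
#' @param marginal Marginal activated fraction over all samples.
#' @param mutant_fraction Fraction of mutant samples.
#' @param or Odds ratio (> 0).
#' @return Named numeric vector `c(p_wt, p_mut)`.
#' @export
cooccurrence_probs <- function(marginal, mutant_fraction, or) {
  if (or <= 0) stop("odds ratio must be > 0", call. = FALSE)
  if (marginal <= 0 || marginal >= 1)
    stop("marginal activated fraction ", marginal,
         " is infeasible for a non-degenerate odds ratio; ",
         "feasible range is the open interval (0, 1)", call. = FALSE)
  f <- mutant_fraction
  g <- function(p0) {
    p1 <- or * p0 / (1 - p0 + or * p0)
    f * p1 + (1 - f) * p0 - marginal
  }
  root <- stats::uniroot(g, c(1e-12, 1 - 1e-12), tol = 1e-12)$root
  p1 <- or * root / (1 - root + or * root)
  c(p_wt = root, p_mut = p1)
}

#' Simulate a mutation-by-activation cohort
#'
#' Background genes are independent Gaussians (per-gene mean drawn once,
#' unit SD); signature genes are shifted by `signature_shift` SDs in
#' planted-activated tumors; activation is sampled conditionally on TP53
#' status with probabilities solved from the marginal fraction and odds
#' ratio; survival is exponential with the double-altered hazard
#' multiplier, censored by an independent exponential. ST samples are drawn
#' from the background (non-activated) distribution and carry
#' `os_time = 0`, `os_event = 0`. Truth labels are emitted in a separate
#' table and never leak into the analyst-facing tables.
#'
#' @param config A [cohort_sim_config()].
#' @return Object of class `sim_cohort`: list with `expression` (matrix),
#'   `clinical`, `mutations`, `gene_set` (the signature genes), `truth`
#'   (sample_id, tp53_mutant, planted_activated, stratum, hazard) and the
#'   `config`.
#' @export
simulate_cohort <- function(config = cohort_sim_config()) {
  stopifnot(inherits(config, "cohort_sim_config"))
  cf <- config
  hcc_ids <- sprintf("HCC%03d", seq_len(cf$n_hcc))
  st_ids <- sprintf("ST%02d", seq_len(cf$n_st))
  sig_genes <- sprintf("SIG%02d", seq_len(cf$n_signature_genes))
  bg_genes <- sprintf("BG%04d", seq_len(cf$n_background_genes))
  genes <- c(sig_genes, bg_genes)

  set.seed(child_seed(cf$seed, 1))
  gene_mean <- stats::rnorm(length(genes), mean = 8, sd = 2)

  set.seed(child_seed(cf$seed, 2))
  n_mut <- round(cf$mutant_fraction * cf$n_hcc)
  mut_ids <- sample(hcc_ids, n_mut)
  class_probs <- c(missense = 0.60, truncating = 0.20, splice = 0.10,
                   inframe = 0.05, deletion_null = 0.05)
  mutations <- data.frame(
    sample_id = mut_ids,
    gene = rep("TP53", n_mut),
    variant_class = sample(names(class_probs), n_mut, replace = TRUE,
                           prob = class_probs),
    stringsAsFactors = FALSE)

  set.seed(child_seed(cf$seed, 3))
  pr <- cooccurrence_probs(cf$activated_fraction, cf$mutant_fraction,
                           cf$cooccurrence_or)
  is_mut <- hcc_ids %in% mut_ids
  activated <- stats::runif(cf$n_hcc) <
    ifelse(is_mut, pr[["p_mut"]], pr[["p_wt"]])

  set.seed(child_seed(cf$seed, 4))
  n_all <- cf$n_hcc + cf$n_st
  expr <- gene_mean + matrix(stats::rnorm(length(genes) * n_all),
                             nrow = length(genes), ncol = n_all)
  dimnames(expr) <- list(genes, c(hcc_ids, st_ids))
  act_ids <- hcc_ids[activated]
  if (length(act_ids))
    expr[sig_genes, act_ids] <- expr[sig_genes, act_ids] + cf$signature_shift

  set.seed(child_seed(cf$seed, 5))
  dbl <- is_mut & activated
  hazard <- cf$baseline_hazard * ifelse(dbl, cf$hazard_multiplier, 1)
  t_event <- stats::rexp(cf$n_hcc, hazard)
  t_cens <- if (cf$censoring_rate > 0) stats::rexp(cf$n_hcc, cf$censoring_rate)
            else rep(Inf, cf$n_hcc)
  os_time <- pmin(t_event, t_cens)
  os_event <- as.integer(t_event <= t_cens)
  clinical <- data.frame(
    sample_id = c(hcc_ids, st_ids),
    sample_type = rep(c("HCC", "ST"), c(cf$n_hcc, cf$n_st)),
    os_time = c(os_time, rep(0, cf$n_st)),
    os_event = c(os_event, rep(0L, cf$n_st)),
    stringsAsFactors = FALSE)

  truth <- data.frame(
    sample_id = hcc_ids,
    tp53_mutant = is_mut,
    planted_activated = activated,
    stratum = paste(ifelse(is_mut, "mut", "wt"),
                    ifelse(activated, "high", "low"), sep = "_"),
    hazard = hazard,
    stringsAsFactors = FALSE)

  structure(list(expression = expr, clinical = clinical,
                 mutations = mutations,
                 gene_set = gene_set("MET_SIGNATURE_SYNTH", sig_genes),
                 truth = truth, config = cf),
            class = "sim_cohort")
}

#' @export
print.sim_cohort <- function(x, ...) {
  cf <- x$config
  cat("Synthetic cohort: ", cf$n_hcc, " HCC + ", cf$n_st, " ST samples, ",
      nrow(x$expression), " genes (", cf$n_signature_genes,
      " signature)\n", sep = "")
  cat(sprintf(
    "  mutant %d/%d, planted activated %d/%d, double-altered %d (seed %d)\n",
    sum(x$truth$tp53_mutant), cf$n_hcc, sum(x$truth$planted_activated),
    cf$n_hcc, sum(x$truth$tp53_mutant & x$truth$planted_activated), cf$seed))
  invisible(x)
}

#' Simulate an RNA-seq-like count experiment with planted DE genes
#'
#' Negative-binomial counts per group (Poisson at dispersion 0), with a
#' planted fraction of genes upregulated in the case group by the stated
#' log2 fold change. The emitted statistic table carries an estimated
#' linear fold change (ratio of group means on the log2(count + 0.5)
#' scale) and a Welch t-test p-value per gene, so the DEG filter can run
#' without any external fitter; planted labels live only in the separate
#' truth table.
#'
#' @param n_genes Number of genes.
#' @param n_per_group Samples per group.
#' @param de_fraction Fraction of genes planted as differential (in
#'   \[0, 1\]).
#' @param log2fc Planted log2 fold change (case over control).
#' @param dispersion NB dispersion (0 = Poisson).
#' @param seed Integer seed.
#' @return List with `counts` (genes x samples), `group`, `stats`
#'   (gene, fold_change, p_value) and `truth` (gene, is_de, true_fc).
#' @export
simulate_deg_counts <- function(n_genes = 2000, n_per_group = 5,
                                de_fraction = 0.1, log2fc = 3,
                                dispersion = 0.05, seed = 1) {
  if (de_fraction < 0 || de_fraction > 1)
    stop("de_fraction must lie in [0, 1]", call. = FALSE)
  stopifnot(n_genes >= 1, n_per_group >= 2, dispersion >= 0)
  set.seed(child_seed(seed, 11))
  genes <- sprintf("G%05d", seq_len(n_genes))
  base <- 2^stats::runif(n_genes, 5, 9)
  n_de <- round(de_fraction * n_genes)
  is_de <- sample(rep(c(TRUE, FALSE), c(n_de, n_genes - n_de)))
  true_fc <- ifelse(is_de, 2^log2fc, 1)
  rcounts <- function(mu) {
    if (dispersion == 0) stats::rpois(length(mu), mu)
    else stats::rnbinom(length(mu), mu = mu, size = 1 / dispersion)
  }
  counts <- cbind(
    matrix(rcounts(rep(base, n_per_group)), ncol = n_per_group),
    matrix(rcounts(rep(base * true_fc, n_per_group)), ncol = n_per_group))
  dimnames(counts) <- list(genes, c(sprintf("ctrl_%d", seq_len(n_per_group)),
                                    sprintf("case_%d", seq_len(n_per_group))))
  group <- factor(rep(c("control", "case"), each = n_per_group),
                  levels = c("control", "case"))

  l <- log2(counts + 0.5)
  i1 <- group == "control"; i2 <- group == "case"
  n <- n_per_group
  m1 <- rowMeans(l[, i1, drop = FALSE]); m2 <- rowMeans(l[, i2, drop = FALSE])
  v1 <- rowSums((l[, i1, drop = FALSE] - m1)^2) / (n - 1)
  v2 <- rowSums((l[, i2, drop = FALSE] - m2)^2) / (n - 1)
  se2 <- v1 / n + v2 / n
  tstat <- (m2 - m1) / sqrt(se2)
  df <- se2^2 / ((v1 / n)^2 / (n - 1) + (v2 / n)^2 / (n - 1))
  p <- 2 * stats::pt(-abs(tstat), df)
  p[!is.finite(p)] <- 1  # zero-variance, equal-mean genes
  p[se2 == 0 & m1 != m2] <- 0
  stats_table <- data.frame(gene = genes, fold_change = 2^(m2 - m1),
                            p_value = p, stringsAsFactors = FALSE)
  truth <- data.frame(gene = genes, is_de = is_de, true_fc = true_fc,
                      stringsAsFactors = FALSE)
  list(counts = counts, group = group, stats = stats_table, truth = truth)
}

#' Simulate a crystal-violet dose-response plate
#'
#' OD readings generated from a 4PL viability curve, scaled so that the
#' vehicle wells have expected OD `vehicle_od`; Gaussian noise (in
#' viability percentage points) is added before scaling. Vehicle wells
#' (concentration 0) are included with the same replication.
#'
#' @param bottom,top,hill,ic50 4PL parameters (viability in percent).
#' @param concentrations Positive concentrations (default: 8 points spread
#'   two decades either side of `ic50`).
#' @param noise_sd Gaussian noise SD in viability percentage points.
#' @param replicates Wells per concentration.
#' @param vehicle_od Expected vehicle OD (absorbance units).
#' @param seed Integer seed.
#' @return Data frame with columns `concentration`, `replicate`, `od`.
#' @export
simulate_dose_response <- function(bottom = 0, top = 100, hill = 1,
                                   ic50 = 16,
                                   concentrations =
                                     ic50 * 10^seq(-2, 2, length.out = 8),
                                   noise_sd = 0, replicates = 3,
                                   vehicle_od = 0.8, seed = 1) {
  stopifnot(ic50 > 0, all(concentrations > 0), replicates >= 1,
            noise_sd >= 0, vehicle_od > 0, top > bottom)
  set.seed(child_seed(seed, 21))
  conc <- rep(c(0, concentrations), each = replicates)
  v <- ifelse(conc == 0, top,
              bottom + (top - bottom) / (1 + (conc / ic50)^hill))
  v <- v + stats::rnorm(length(v), 0, noise_sd)
  data.frame(concentration = conc,
             replicate = rep_len(seq_len(replicates), length(conc)),
             od = vehicle_od * v / top)
}
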