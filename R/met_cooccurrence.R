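# The end-to-end co-occurrence analysis as a single fitting-style entry
# point: standardize -> score -> threshold -> classify -> TP53 status ->
# stratify -> crosstab -> score comparison -> KM / log-rank.

#' c-MET activation by TP53 mutation co-occurrence analysis
#'
#' Runs the full cohort analysis: per-gene standardization against the
#' chosen reference population, signature scoring, the ST-referenced
#' activation threshold (mean + k SD), per-HCC activation calls, TP53
#' stratification, the 2x2 co-occurrence crosstab with odds ratio, a
#' two-sided score comparison between mutant and wild-type tumors, and
#' Kaplan-Meier / log-rank survival comparison of the double-altered
#' stratum against the rest (or all pairwise stratum contrasts).
#'
#' @param expr Gene x sample expression matrix (see [read_expression()]).
#' @param clinical Clinical table (see [read_clinical()]).
#' @param mutations Mutation table (see [read_mutations()]).
#' @param gene_set Signature [gene_set()] or character vector of symbols.
#' @param k Threshold multiplier on the ST score SD (default 1.5).
#' @param reference Standardization reference population: `"all"` samples
#'   (default), `"st"` or `"hcc"`.
#' @param null_definition Variant classes counted as TP53-null (see
#'   [assign_tp53_status()]).
#' @param min_genes Minimum signature genes required (default: all).
#' @param contrast `"double_vs_rest"` (default) compares the
#'   mutant/activated stratum against the pooled other three;
#'   `"pairwise"` additionally reports unadjusted pairwise log-rank tests.
#' @param score_test Method for the mutant-vs-wild-type score comparison
#'   (default Student's t-test).
#' @param ddof Delta degrees of freedom for all SDs (default 1).
#' @return Object of class `met_cooccurrence`: list with `scores`,
#'   `threshold`, `activation`, `strata`, `crosstab`, `score_test`,
#'   `survival` (joined stratum/survival table), `km` (per-stratum
#'   curves), `logrank`, optional `pairwise`, `n_dropped_survival`, `call`.
#' @export
met_cooccurrence <- function(expr, clinical, mutations, gene_set,
                             k = 1.5, reference = c("all", "st", "hcc"),
                             null_definition = c("truncating", "splice",
                                                 "deletion_null"),
                             min_genes = NULL,
                             contrast = c("double_vs_rest", "pairwise"),
                             score_test = c("student", "welch",
                                            "mann_whitney"),
                             ddof = 1) {
  reference <- match.arg(reference)
  contrast <- match.arg(contrast)
  score_test <- match.arg(score_test)
  ref_ids <- switch(reference,
                    all = colnames(expr),
                    st = clinical$sample_id[clinical$sample_type == "ST"],
                    hcc = clinical$sample_id[clinical$sample_type == "HCC"])
  ref_ids <- intersect(colnames(expr), ref_ids)
  z <- standardize(expr, ref_ids, ddof = ddof)
  sc <- signature_score(z, gene_set, min_genes = min_genes)
  tau <- activation_threshold(sc, clinical, k = k)
  act <- classify_met(sc, clinical, tau)
  status <- assign_tp53_status(mutations, act$sample_id,
                               null_definition = null_definition)
  strata <- stratify(status, act)
  xt <- crosstab(strata)

  mut_scores <- strata$score[strata$tp53_status == "mutant"]
  wt_scores <- strata$score[strata$tp53_status == "wild_type"]
  cmp <- if (length(mut_scores) >= 2L && length(wt_scores) >= 2L)
    compare_scores(mut_scores, wt_scores, method = score_test)
  else NULL

  surv <- merge(as.data.frame(strata),
                clinical[, c("sample_id", "os_time", "os_event")],
                by = "sample_id")
  ok <- is.finite(surv$os_time) & !is.na(surv$os_event)
  n_dropped <- sum(!ok)
  surv <- surv[ok, , drop = FALSE]

  km <- lapply(split(surv, surv$stratum),
               function(d) km_estimate(d$os_time, d$os_event))
  grp <- ifelse(surv$stratum == "mut_high", "mut_high", "rest")
  lr <- if (length(unique(grp)) == 2L && sum(surv$os_event) > 0L)
    logrank_test(surv$os_time, surv$os_event, grp)
  else NULL

  pairwise <- NULL
  if (contrast == "pairwise") {
    strata_names <- sort(unique(surv$stratum))
    pairs <- utils::combn(strata_names, 2, simplify = FALSE)
    pairwise <- lapply(pairs, function(pr) {
      d <- surv[surv$stratum %in% pr, , drop = FALSE]
      if (sum(d$os_event) > 0L && length(unique(d$stratum)) == 2L)
        logrank_test(d$os_time, d$os_event, d$stratum)
      else NULL
    })
    names(pairwise) <- vapply(pairs, paste, character(1), collapse = " vs ")
  }

  structure(list(scores = sc, threshold = tau, activation = act,
                 strata = strata, crosstab = xt, score_test = cmp,
                 survival = surv, km = km, logrank = lr,
                 pairwise = pairwise, n_dropped_survival = n_dropped,
                 reference = reference, call = match.call()),
            class = "met_cooccurrence")
}

#' @export
print.met_cooccurrence <- function(x, ...) {
  cat("c-MET / TP53 co-occurrence analysis\n")
  cat(sprintf("  %d HCC samples classified (tau = %.4g, k = %g, n_ST = %d)\n",
              nrow(x$activation), attr(x$activation, "tau"),
              attr(x$threshold, "k"), attr(x$threshold, "n_st")))
  rp <- x$crosstab$row_proportions
  cnt <- x$crosstab$counts
  cat(sprintf("  c-MET high: %.1f%% of mutant (%d/%d), %.1f%% of wild-type (%d/%d); OR = %.3g\n",
              100 * rp["mutant", "high"], cnt["mutant", "high"],
              sum(cnt["mutant", ]),
              100 * rp["wild_type", "high"], cnt["wild_type", "high"],
              sum(cnt["wild_type", ]), x$crosstab$odds_ratio))
  if (!is.null(x$score_test))
    cat(sprintf("  score, mutant vs wild-type (%s): p = %.3g\n",
                x$score_test$method, x$score_test$p_value))
  if (!is.null(x$logrank))
    cat(sprintf("  log-rank, double-altered vs rest: chi-square = %.3f, p = %.3g\n",
                x$logrank$statistic, x$logrank$p_value))
  invisible(x)
}

#' @export
summary.met_cooccurrence <- function(object, ...) {
  print(object)
  cat("\nStratum sizes:\n")
  print(table(object$strata$stratum))
  cat("\n")
  print(object$crosstab)
  if (!is.null(object$logrank)) { cat("\n"); print(object$logrank) }
  if (object$n_dropped_survival > 0)
    cat("\nSamples dropped from survival (missing follow-up): ",
        object$n_dropped_survival, "\n", sep = "")
  invisible(object)
}

#' Plot Kaplan-Meier curves per stratum
#'
#' @param x A `met_cooccurrence` object.
#' @param ... Passed to [plot.met_km()].
#' @return `x`, invisibly.
#' @export
plot.met_cooccurrence <- function(x, ...) {
  strata <- names(x$km)
  cols <- seq_along(strata)
  first <- TRUE
  for (i in seq_along(strata)) {
    plot(x$km[[i]], add = !first, col = cols[i],
         xlab = "Time (months)", ylab = "Overall survival", ...)
    first <- FALSE
  }
  graphics::legend("bottomleft", legend = strata, col = cols, lwd = 2,
                   bty = "n")
  invisible(x)
}
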