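# TP53-by-c-MET stratification, the 2x2 co-occurrence crosstab, the
# Kaplan-Meier product-limit estimator and the log-rank (Mantel-Cox) test.
# KM and log-rank are computed from first principles; at tied times events
# precede censoring in the risk-set accounting.

#' Assign TP53 mutation status per sample
#'
#' A sample is `mutant` iff it carries at least one record for `gene` of any
#' variant class; samples absent from the mutation table are `wild_type` by
#' contract. A sample is additionally flagged "null" iff any of its records
#' falls in `null_definition` (loss-of-function classes by default).
#'
#' @param mutations Mutation table from [read_mutations()].
#' @param samples Character vector of sample ids to classify.
#' @param gene Gene symbol to test (default `"TP53"`).
#' @param null_definition Variant classes counted as null alleles
#'   (default `truncating`, `splice`, `deletion_null`).
#' @return Data frame with columns `sample_id`, `tp53_status`
#'   (`mutant`/`wild_type`), `tp53_null` (logical) and `variant_classes`
#'   (comma-separated, empty for wild-type).
#' @export
assign_tp53_status <- function(mutations, samples, gene = "TP53",
                               null_definition = c("truncating", "splice",
                                                   "deletion_null")) {
  bad <- setdiff(null_definition, VARIANT_CLASSES)
  if (length(bad))
    stop("unknown variant class(es) in null_definition: ",
         paste(bad, collapse = ", "), call. = FALSE)
  samples <- as.character(samples)
  rec <- mutations[mutations$gene == gene &
                     mutations$sample_id %in% samples, , drop = FALSE]
  classes <- split(as.character(rec$variant_class), rec$sample_id)
  has <- samples %in% names(classes)
  tp53_null <- logical(length(samples))
  cls_str <- character(length(samples))
  for (i in which(has)) {
    cl <- classes[[samples[i]]]
    tp53_null[i] <- any(cl %in% null_definition)
    cls_str[i] <- paste(sort(unique(cl)), collapse = ",")
  }
  data.frame(sample_id = samples,
             tp53_status = ifelse(has, "mutant", "wild_type"),
             tp53_null = tp53_null,
             variant_classes = cls_str,
             stringsAsFactors = FALSE)
}

#' Build the four-way TP53 x c-MET strata
#'
#' Joins per-sample TP53 status with activation calls into the strata
#' `mut_high`, `mut_low`, `wt_high`, `wt_low`. Samples present in only one
#' input are excluded and reported in the `excluded` attribute.
#'
#' @param status Data frame from [assign_tp53_status()].
#' @param calls Activation calls from [classify_met()].
#' @return Data frame of class `met_strata` with columns `sample_id`,
#'   `tp53_status`, `tp53_null`, `variant_classes`, `score`, `met_class`,
#'   `stratum`.
#' @export
stratify <- function(status, calls) {
  calls_df <- as.data.frame(calls)[, c("sample_id", "score", "met_class")]
  merged <- merge(status, calls_df, by = "sample_id", sort = TRUE)
  if (!nrow(merged))
    stop("no samples carry both a TP53 status and a c-MET class", call. = FALSE)
  merged$stratum <- paste(ifelse(merged$tp53_status == "mutant", "mut", "wt"),
                          merged$met_class, sep = "_")
  excluded <- list(status_only = setdiff(status$sample_id, calls_df$sample_id),
                   calls_only = setdiff(calls_df$sample_id, status$sample_id))
  structure(merged, excluded = excluded,
            class = c("met_strata", "data.frame"))
}

#' 2x2 co-occurrence crosstab
#'
#' Counts, within-row and within-column proportions and the odds ratio of
#' TP53 status against c-MET class. With a zero cell the odds ratio uses a
#' Haldane correction of 0.5 per cell and is flagged as corrected.
#'
#' @param x A `met_strata` data frame from [stratify()], or a 2x2 matrix of
#'   counts with rows (mutant, wild_type) and columns (high, low).
#' @return Object of class `met_crosstab`: list with elements `counts`,
#'   `row_proportions`, `col_proportions`, `odds_ratio`,
#'   `haldane_corrected`, `n`.
#' @export
crosstab <- function(x) {
  if (is.matrix(x) || is.table(x)) {
    if (!all(dim(x) == c(2L, 2L)))
      stop("count matrix must be 2x2 (TP53 status x c-MET class)",
           call. = FALSE)
    counts <- as.table(matrix(as.numeric(x), 2, 2, dimnames = list(
      tp53 = c("mutant", "wild_type"), met = c("high", "low"))))
  } else {
    if (!nrow(x)) stop("empty stratum table", call. = FALSE)
    counts <- table(tp53 = factor(x$tp53_status, c("mutant", "wild_type")),
                    met = factor(x$met_class, c("high", "low")))
  }
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  a <- counts["mutant", "high"]; b <- counts["mutant", "low"]
  c0 <- counts["wild_type", "high"]; d <- counts["wild_type", "low"]
  corrected <- any(counts == 0)
  if (corrected) { a <- a + 0.5; b <- b + 0.5; c0 <- c0 + 0.5; d <- d + 0.5 }
  structure(list(counts = counts,
                 row_proportions = prop.table(counts, 1),
                 col_proportions = prop.table(counts, 2),
                 odds_ratio = (a * d) / (b * c0),
                 haldane_corrected = corrected,
                 n = sum(counts)),
            class = "met_crosstab")
}

#' @export
print.met_crosstab <- function(x, ...) {
  cat("TP53 x c-MET crosstab (n = ", x$n, ")\n", sep = "")
  print(x$counts)
  cat("\nRow proportions (within TP53 status):\n")
  print(round(x$row_proportions, 4))
  cat(sprintf("\nOdds ratio: %.4g%s\n", x$odds_ratio,
              if (x$haldane_corrected) " (Haldane 0.5 corrected)" else ""))
  invisible(x)
}

#' Kaplan-Meier product-limit estimator
#'
#' Survival is re-estimated at each distinct observed time; censored-only
#' times leave the estimate unchanged and affect the risk sets only. Ties
#' between events and censoring at the same time are resolved with events
#' first (both remain in the risk set at that time).
#'
#' @param times Non-negative follow-up times.
#' @param events Event indicators (1 = event, 0 = censored).
#' @return Data frame of class `met_km` with columns `time`, `n_risk`,
#'   `n_event`, `n_censored`, `survival`; S(0) = 1 implicitly.
#' @export
km_estimate <- function(times, events) {
  times <- as.numeric(times); events <- as.integer(events)
  if (!length(times)) stop("empty survival input", call. = FALSE)
  if (length(times) != length(events))
    stop("times and events differ in length", call. = FALSE)
  if (any(!is.finite(times)) || any(times < 0))
    stop("times must be finite and >= 0", call. = FALSE)
  if (!all(events %in% c(0L, 1L)))
    stop("events must be 0 or 1", call. = FALSE)
  ut <- sort(unique(times))
  n_risk <- vapply(ut, function(x) sum(times >= x), integer(1))
  n_event <- vapply(ut, function(x) sum(events[times == x] == 1L), integer(1))
  n_cens <- vapply(ut, function(x) sum(events[times == x] == 0L), integer(1))
  surv <- cumprod(1 - n_event / n_risk)
  out <- data.frame(time = ut, n_risk = n_risk, n_event = n_event,
                    n_censored = n_cens, survival = surv)
  structure(out, n = length(times), n_events = sum(n_event),
            class = c("met_km", "data.frame"))
}

#' @export
plot.met_km <- function(x, add = FALSE, col = 1, lwd = 2,
                        xlab = "Time", ylab = "Survival", ...) {
  sx <- c(0, rep(x$time, each = 2))
  sy <- c(1, 1, rep(x$survival[-nrow(x)], each = 2), x$survival[nrow(x)])
  if (!add)
    graphics::plot(sx, sy, type = "n", ylim = c(0, 1), xlab = xlab,
                   ylab = ylab, ...)
  graphics::lines(sx, sy, col = col, lwd = lwd)
  invisible(x)
}

#' Log-rank (Mantel-Cox) test
#'
#' Compares the survival distributions of two or more groups using
#' hypergeometric expected event counts and variances at each distinct
#' event time; the chi-square statistic is the quadratic form of the
#' observed-minus-expected vector against its covariance, with
#' groups - 1 degrees of freedom.
#'
#' @param times Non-negative follow-up times.
#' @param events Event indicators (1 = event, 0 = censored).
#' @param group Group label per observation (>= 2 non-empty groups).
#' @return Object of class `met_logrank`: list with `statistic`, `df`,
#'   `p_value`, `observed`, `expected` (named per group), `n`.
#' @export
logrank_test <- function(times, events, group) {
  times <- as.numeric(times); events <- as.integer(events)
  g <- droplevels(factor(group))
  k <- nlevels(g)
  if (k < 2L) stop("log-rank needs at least 2 groups", call. = FALSE)
  if (length(times) != length(events) || length(times) != length(g))
    stop("times, events and group differ in length", call. = FALSE)
  if (sum(events) < 1L)
    stop("log-rank needs at least one event", call. = FALSE)
  lev <- levels(g)
  ut <- sort(unique(times[events == 1L]))
  O <- E <- numeric(k)
  V <- matrix(0, k, k)
  for (tj in ut) {
    at <- times >= tj
    nj <- sum(at)
    is_ev <- events == 1L & times == tj
    dj <- sum(is_ev)
    ngj <- vapply(lev, function(l) sum(at & g == l), numeric(1))
    dgj <- vapply(lev, function(l) sum(is_ev & g == l), numeric(1))
    O <- O + dgj
    E <- E + dj * ngj / nj
    if (nj > 1L) {
      p <- ngj / nj
      V <- V + dj * (nj - dj) / (nj - 1) * (diag(p, nrow = k) - tcrossprod(p))
    }
  }
  idx <- seq_len(k - 1L)
  U <- (O - E)[idx]
  Vi <- V[idx, idx, drop = FALSE]
  chisq <- tryCatch(drop(crossprod(U, solve(Vi, U))),
                    error = function(e) NA_real_)
  if (!is.finite(chisq)) {  # singular covariance: pseudo-inverse
    s <- svd(Vi)
    pos <- s$d > max(1e-12 * s$d[1], 0)
    pinv <- s$v[, pos, drop = FALSE] %*%
      (t(s$u[, pos, drop = FALSE]) / s$d[pos])
    chisq <- drop(crossprod(U, pinv %*% U))
  }
  structure(list(statistic = chisq,
                 df = k - 1L,
                 p_value = stats::pchisq(chisq, k - 1L, lower.tail = FALSE),
                 observed = stats::setNames(O, lev),
                 expected = stats::setNames(E, lev),
                 n = length(times)),
            class = "met_logrank")
}

#' @export
print.met_logrank <- function(x, ...) {
  cat("Log-rank (Mantel-Cox) test\n")
  print(data.frame(group = names(x$observed), observed = x$observed,
                   expected = round(x$expected, 3), row.names = NULL))
  cat(sprintf("Chi-square = %.4f, df = %d, p = %.4g\n",
              x$statistic, x$df, x$p_value))
  invisible(x)
}

#' Two-sample score comparison
#'
#' Two-sided comparison of two numeric vectors by Student's t-test (pooled
#' variance), Welch's t-test or the Mann-Whitney rank test.
#'
#' @param a,b Numeric vectors (length >= 2 for the t variants, >= 1 for the
#'   rank test).
#' @param method One of `"student"`, `"welch"`, `"mann_whitney"`.
#' @return List with `statistic`, `p_value`, `method`, `n` (group sizes)
#'   and `means`.
#' @export
compare_scores <- function(a, b, method = c("student", "welch",
                                            "mann_whitney")) {
  method <- match.arg(method)
  a <- as.numeric(a); b <- as.numeric(b)
  if (method %in% c("student", "welch")) {
    if (length(a) < 2L || length(b) < 2L)
      stop("t-based methods need at least 2 values per group", call. = FALSE)
    if (stats::var(a) == 0 && stats::var(b) == 0)
      stop("both groups have zero variance; use method = 'mann_whitney'",
           call. = FALSE)
    ht <- stats::t.test(a, b, var.equal = (method == "student"))
  } else {
    if (!length(a) || !length(b))
      stop("mann_whitney needs at least 1 value per group", call. = FALSE)
    ht <- stats::wilcox.test(a, b)
  }
  list(statistic = unname(ht$statistic),
       p_value = ht$p.value,
       method = method,
       n = c(length(a), length(b)),
       means = c(mean(a), mean(b)))
}
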