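# Crystal-violet viability normalization, four-parameter-logistic (4PL)
# dose-response fitting with a relative IC50, caliper tumor volumes
# (V = A * B^2 / 2) and endpoint group comparisons.

#' Normalize OD readings to percent viability
#'
#' Viability = 100 * OD / mean(vehicle OD), where vehicle wells are those
#' with concentration 0; vehicle wells therefore average to 100 by
#' construction. When `cell_line` and/or `drug` columns are present the
#' normalization is done within each (cell line, drug) group. No
#' background subtraction is applied.
#'
#' @param table Data frame with numeric columns `concentration` (>= 0,
#'   0 = vehicle) and `od`, plus optional `cell_line`/`drug` labels.
#' @return The input table with an added `viability` column (percent).
#' @export
normalize_viability <- function(table) {
  req <- c("concentration", "od")
  miss <- setdiff(req, names(table))
  if (length(miss))
    stop("dose-response table missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  conc <- as.numeric(table$concentration)
  od <- as.numeric(table$od)
  if (anyNA(conc) || any(conc < 0))
    stop("concentration must be numeric and >= 0", call. = FALSE)
  by_cols <- intersect(c("cell_line", "drug"), names(table))
  f <- if (length(by_cols)) interaction(table[by_cols], drop = TRUE)
       else factor(rep.int(1L, nrow(table)))
  table$viability <- NA_real_
  for (lev in levels(f)) {
    i <- f == lev
    veh <- od[i & conc == 0]
    if (!length(veh))
      stop("no vehicle (concentration 0) wells",
           if (length(by_cols)) paste0(" in group '", lev, "'") else "",
           call. = FALSE)
    m <- mean(veh)
    if (m == 0) stop("vehicle mean OD is zero; cannot normalize",
                     call. = FALSE)
    table$viability[i] <- 100 * od[i] / m
  }
  table
}

#' Fit a four-parameter logistic dose-response curve
#'
#' Least-squares fit of
#' `v(c) = bottom + (top - bottom) / (1 + (c / ic50)^hill)`
#' on log10 concentration. The IC50 is the curve's inflection concentration
#' (relative IC50); the absolute-50% crossing is reported as a derived
#' field when it exists. Initialization is deterministic (top = max v,
#' bottom = min v, hill = 1, ic50 = the geometric median concentration)
#' with a fixed grid of hill restarts; non-convergence is flagged on the
#' result, not raised.
#'
#' @param conc Concentrations (vehicle, c = 0, is excluded from the fit).
#' @param viability Percent viability per well.
#' @param init Optional named list overriding initial values (`bottom`,
#'   `top`, `hill`, `ic50`).
#' @return Object of class `fit4pl` with `coefficients`
#'   (bottom, top, hill, ic50), `rss`, `sigma`, `converged`, `degenerate`,
#'   `ic50_absolute`, the fitting data, fitted values and residuals.
#' @export
fit_4pl <- function(conc, viability, init = NULL) {
  conc <- as.numeric(conc); viability <- as.numeric(viability)
  if (length(conc) != length(viability))
    stop("conc and viability differ in length", call. = FALSE)
  if (any(!is.finite(conc)) || any(conc < 0))
    stop("concentrations must be finite and >= 0", call. = FALSE)
  pos <- conc > 0
  d <- data.frame(conc = conc[pos], lc = log10(conc[pos]), v = viability[pos])
  if (length(unique(d$lc)) < 4L)
    stop("need at least 4 distinct positive concentrations", call. = FALSE)
  start0 <- list(bottom = min(d$v), top = max(d$v), hill = 1,
                 lic50 = stats::median(unique(d$lc)))
  if (!is.null(init)) {
    if (!is.null(init$ic50)) { init$lic50 <- log10(init$ic50); init$ic50 <- NULL }
    start0[names(init)] <- init
  }
  starts <- lapply(c(start0$hill, 0.5, 2, -1), function(h) {
    s <- start0; s$hill <- h; s
  })
  model4pl <- function(p, lc)
    p[["bottom"]] + (p[["top"]] - p[["bottom"]]) /
      (1 + 10^(p[["hill"]] * (lc - p[["lic50"]])))
  try_fit <- function(s) {
    r <- tryCatch(
      minpack.lm::nls.lm(par = unlist(s),
                         fn = function(p) d$v - model4pl(p, d$lc),
                         control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL)
    if (!is.null(r) && all(is.finite(unlist(r$par)))) r else NULL
  }
  fit <- NULL
  for (s in starts) {  # deterministic restart grid; keep the best deviance
    r <- try_fit(s)
    if (!is.null(r) && (is.null(fit) || r$deviance < fit$deviance)) fit <- r
  }
  if (!is.null(fit)) {  # polish from the best estimate
    polished <- try_fit(as.list(fit$par))
    if (!is.null(polished) && polished$deviance <= fit$deviance)
      fit <- polished
  }
  if (is.null(fit)) {
    cf <- c(bottom = start0$bottom, top = start0$top, hill = NA_real_,
            ic50 = NA_real_)
    res <- structure(list(coefficients = cf, log10_ic50 = NA_real_,
                          rss = NA_real_, sigma = NA_real_,
                          converged = FALSE, degenerate = TRUE,
                          ic50_absolute = NA_real_, data = d,
                          fitted.values = rep(NA_real_, nrow(d)),
                          residuals = rep(NA_real_, nrow(d)),
                          call = match.call()),
                     class = "fit4pl")
    return(res)
  }
  cf <- unlist(fit$par)
  bottom <- unname(cf["bottom"]); top <- unname(cf["top"])
  hill <- unname(cf["hill"]); lic50 <- unname(cf["lic50"])
  if (bottom > top) {  # equivalent parameterisation with bottom <= top
    tmp <- bottom; bottom <- top; top <- tmp; hill <- -hill
  }
  fitted <- model4pl(as.list(cf), d$lc)
  resid <- d$v - fitted
  rss <- sum(resid^2)
  n <- nrow(d)
  sigma <- if (n > 4L) sqrt(rss / (n - 4L)) else NA_real_
  degenerate <- !is.finite(top - bottom) ||
    (top - bottom) < 1e-6 * max(1, abs(top))
  ic50_abs <- if (is.finite(bottom) && is.finite(top) &&
                  bottom < 50 && top > 50 && hill != 0)
    10^(lic50 + log10((top - 50) / (50 - bottom)) / hill)
  else NA_real_
  structure(list(coefficients = c(bottom = bottom, top = top, hill = hill,
                                  ic50 = 10^lic50),
                 log10_ic50 = lic50,
                 rss = rss, sigma = sigma,
                 converged = fit$info %in% 1:3 && !degenerate,
                 degenerate = degenerate,
                 ic50_absolute = ic50_abs,
                 data = d,
                 fitted.values = fitted,
                 residuals = resid,
                 call = match.call()),
            class = "fit4pl")
}

#' @export
coef.fit4pl <- function(object, ...) object$coefficients

#' @export
fitted.fit4pl <- function(object, ...) object$fitted.values

#' @export
residuals.fit4pl <- function(object, ...) object$residuals

#' Predict viability from a 4PL fit
#'
#' @param object A `fit4pl` object.
#' @param newdata Optional numeric vector of concentrations (or a data
#'   frame with a `conc` column); defaults to the fitting concentrations.
#' @param ... Unused.
#' @return Numeric vector of predicted percent viabilities.
#' @export
predict.fit4pl <- function(object, newdata = NULL, ...) {
  conc <- if (is.null(newdata)) object$data$conc
          else if (is.data.frame(newdata)) as.numeric(newdata$conc)
          else as.numeric(newdata)
  cf <- object$coefficients
  ifelse(conc == 0, cf["top"],
         cf["bottom"] + (cf["top"] - cf["bottom"]) /
           (1 + (conc / cf["ic50"])^cf["hill"]))
}

#' @export
print.fit4pl <- function(x, ...) {
  cf <- x$coefficients
  cat("Four-parameter logistic dose-response fit\n")
  cat(sprintf("  bottom = %.4g%%, top = %.4g%%, hill = %.4g, IC50 = %.6g\n",
              cf["bottom"], cf["top"], cf["hill"], cf["ic50"]))
  cat(sprintf("  RSS = %.4g, converged: %s%s\n", x$rss, x$converged,
              if (x$degenerate) " (degenerate: flat response)" else ""))
  invisible(x)
}

#' @export
summary.fit4pl <- function(object, ...) {
  cf <- object$coefficients
  cat("4PL fit on", nrow(object$data), "wells,",
      length(unique(object$data$conc)), "concentrations\n")
  print(cf)
  cat(sprintf("relative IC50 = %.6g, absolute IC50 = %.6g\n",
              cf["ic50"], object$ic50_absolute))
  cat(sprintf("RSS = %.6g, residual sigma = %.4g, converged = %s\n",
              object$rss, object$sigma, object$converged))
  invisible(object)
}

#' @export
plot.fit4pl <- function(x, n_curve = 200, xlab = "Concentration",
                        ylab = "Viability (%)", ...) {
  d <- x$data
  graphics::plot(d$conc, d$v, log = "x", xlab = xlab, ylab = ylab, ...)
  cgrid <- 10^seq(min(d$lc), max(d$lc), length.out = n_curve)
  graphics::lines(cgrid, predict(x, cgrid), lwd = 2)
  graphics::abline(v = x$coefficients["ic50"], lty = 2)
  invisible(x)
}

#' Simulate responses from a fitted 4PL model
#'
#' Draws Gaussian noise with the fit's residual sigma around the fitted
#' curve at the fitting concentrations.
#'
#' @param object A converged `fit4pl` object.
#' @param nsim Number of simulated response vectors.
#' @param seed Optional seed.
#' @param ... Unused.
#' @return Data frame with one column per simulation.
#' @export
simulate.fit4pl <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  if (!is.finite(object$sigma))
    stop("fit has no residual sigma to simulate from", call. = FALSE)
  mu <- object$fitted.values
  out <- as.data.frame(replicate(nsim, mu + stats::rnorm(length(mu), 0,
                                                         object$sigma)))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' Caliper tumor volume
#'
#' V = A * B^2 / 2 with A the largest and B the smallest diameter.
#' Measurements supplied with A < B are swapped with a warning; vectors
#' recycle as usual.
#'
#' @param A Largest diameter (mm, > 0).
#' @param B Smallest diameter (mm, > 0).
#' @return Tumor volume(s) in mm^3.
#' @export
tumor_volume <- function(A, B) {
  A <- as.numeric(A); B <- as.numeric(B)
  if (length(A) != length(B))
    stop("A and B differ in length", call. = FALSE)
  if (any(!is.finite(A)) || any(!is.finite(B)) || any(A <= 0) || any(B <= 0))
    stop("diameters must be finite and positive", call. = FALSE)
  swap <- A < B
  if (any(swap)) {
    warning(sum(swap),
            " measurement(s) had A < B; diameters swapped so A is largest",
            call. = FALSE)
    tmp <- A[swap]; A[swap] <- B[swap]; B[swap] <- tmp
  }
  A * B^2 / 2
}

#' Endpoint comparison of tumor growth between groups
#'
#' At the stated day, computes per-group mean and SD of tumor volume and a
#' two-sided test via [compare_scores()]. With more than two groups every
#' non-reference group is tested against the reference (unadjusted).
#'
#' @param measurements Data frame with columns `mouse_id`, `group`, `day`,
#'   and either `volume` or the diameters `A` and `B` (volumes then
#'   computed with [tumor_volume()]).
#' @param day Endpoint day to compare.
#' @param method Test passed to [compare_scores()].
#' @param reference Reference group label (default: first group).
#' @return List with `day`, `summary` (group, n, mean, sd) and `tests`
#'   (one [compare_scores()] result per contrast).
#' @export
growth_endpoint_test <- function(measurements, day,
                                 method = c("student", "welch",
                                            "mann_whitney"),
                                 reference = NULL) {
  method <- match.arg(method)
  req <- c("mouse_id", "group", "day")
  miss <- setdiff(req, names(measurements))
  if (length(miss))
    stop("measurement table missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (!"volume" %in% names(measurements)) {
    if (!all(c("A", "B") %in% names(measurements)))
      stop("need a 'volume' column or diameters 'A' and 'B'", call. = FALSE)
    measurements$volume <- tumor_volume(measurements$A, measurements$B)
  }
  sel <- measurements$day == day
  if (!any(sel))
    stop("no measurements at day ", day, "; available days: ",
         paste(sort(unique(measurements$day)), collapse = ", "),
         call. = FALSE)
  d <- measurements[sel, , drop = FALSE]
  groups <- split(d$volume, as.character(d$group))
  if (length(groups) < 2L)
    stop("need at least 2 groups at day ", day, call. = FALSE)
  small <- names(groups)[lengths(groups) < 2L]
  if (length(small))
    stop("group(s) with fewer than 2 animals at day ", day, ": ",
         paste(small, collapse = ", "), call. = FALSE)
  summ <- data.frame(group = names(groups),
                     n = lengths(groups),
                     mean = vapply(groups, mean, numeric(1)),
                     sd = vapply(groups, stats::sd, numeric(1)),
                     row.names = NULL)
  reference <- reference %||% names(groups)[1L]
  if (!reference %in% names(groups))
    stop("reference group '", reference, "' absent at day ", day,
         call. = FALSE)
  others <- setdiff(names(groups), reference)
  tests <- lapply(others, function(gp)
    compare_scores(groups[[reference]], groups[[gp]], method = method))
  names(tests) <- paste(reference, "vs", others)
  list(day = day, summary = summ, tests = tests)
}
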