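# Per-sample c-MET signature scoring: per-gene standardization against a
# reference population, unweighted mean over the signature genes, and an
# activation call against the surrounding-tissue (ST) referenced threshold
# tau = mean(ST scores) + k * SD(ST scores).

#' Standardize an expression matrix per gene
#'
#' Each gene is z-transformed using the mean and sample SD computed over a
#' reference population of samples (default: all samples). Genes with zero
#' variance in the reference are dropped and reported in the
#' `dropped_genes` attribute.
#'
#' @param expr Numeric matrix, genes in rows, samples in columns.
#' @param reference Character vector of sample ids defining the reference
#'   population; `NULL` (default) uses all samples.
#' @param ddof Delta degrees of freedom for the SD: 1 (default) gives the
#'   sample SD, 0 the population SD.
#' @return Matrix of class `met_zmatrix` with attributes `reference`,
#'   `ref_mean`, `ref_sd`, `ddof` and `dropped_genes`.
#' @export
standardize <- function(expr, reference = NULL, ddof = 1) {
  stopifnot(is.matrix(expr), is.numeric(expr))
  if (is.null(rownames(expr)) || is.null(colnames(expr)))
    stop("expression matrix needs gene rownames and sample colnames",
         call. = FALSE)
  samples <- colnames(expr)
  if (is.null(reference)) reference <- samples
  missing <- setdiff(reference, samples)
  if (length(missing))
    stop("reference sample(s) absent from matrix: ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  n <- length(reference)
  if (n < 2L)
    stop("standardization reference needs at least 2 samples (SD undefined)",
         call. = FALSE)
  ref <- expr[, reference, drop = FALSE]
  mu <- rowMeans(ref)
  sdv <- sqrt(rowSums((ref - mu)^2) / (n - ddof))
  drop <- !is.finite(sdv) | sdv == 0
  dropped <- rownames(expr)[drop]
  if (all(drop))
    stop("all genes have zero variance in the reference population",
         call. = FALSE)
  z <- (expr[!drop, , drop = FALSE] - mu[!drop]) / sdv[!drop]
  structure(z,
            reference = reference,
            ref_mean = mu[!drop],
            ref_sd = sdv[!drop],
            ddof = ddof,
            dropped_genes = dropped,
            class = c("met_zmatrix", class(z)))
}

#' @export
print.met_zmatrix <- function(x, ...) {
  cat("Standardized expression: ", nrow(x), " genes x ", ncol(x),
      " samples (reference n = ", length(attr(x, "reference")),
      ", ddof = ", attr(x, "ddof"), ")\n", sep = "")
  dg <- attr(x, "dropped_genes")
  if (length(dg))
    cat("Dropped zero-variance genes: ", paste(dg, collapse = ", "), "\n",
        sep = "")
  invisible(x)
}

#' Per-sample signature score
#'
#' Unweighted mean of the standardized values of the signature's member
#' genes (every gene carries weight 1), per sample. By default all members
#' must be present in the matrix; lower `min_genes` to score over the
#' present subset, with the missing symbols recorded.
#'
#' @param z Standardized matrix from [standardize()] (any gene x sample
#'   numeric matrix works).
#' @param set A [gene_set()] or character vector of member symbols.
#' @param min_genes Minimum number of members that must be present
#'   (default: all of them).
#' @return Named numeric vector of class `met_scores` (one score per
#'   sample, input order preserved) with attributes `set_name`,
#'   `n_genes_used` and `missing_genes`.
#' @export
signature_score <- function(z, set, min_genes = NULL) {
  genes <- if (inherits(set, "gene_set")) set$genes else as.character(set)
  set_name <- if (inherits(set, "gene_set")) set$name else "custom"
  genes <- unique(genes)
  present <- intersect(genes, rownames(z))
  missing <- setdiff(genes, rownames(z))
  if (is.null(min_genes)) min_genes <- length(genes)
  if (length(present) < min_genes)
    stop(sprintf(
      "only %d of %d signature genes present (min_genes = %d); missing: %s",
      length(present), length(genes), min_genes,
      paste(missing, collapse = ", ")), call. = FALSE)
  score <- colMeans(z[present, , drop = FALSE])
  structure(score,
            set_name = set_name,
            n_genes_used = length(present),
            missing_genes = missing,
            class = "met_scores")
}

#' @export
print.met_scores <- function(x, ...) {
  cat("Signature scores for set '", attr(x, "set_name"), "' (",
      attr(x, "n_genes_used"), " genes, ", length(x), " samples)\n", sep = "")
  mg <- attr(x, "missing_genes")
  if (length(mg))
    cat("Missing members: ", paste(mg, collapse = ", "), "\n", sep = "")
  print(stats::setNames(as.numeric(x), names(x)), ...)
  invisible(x)
}

#' Activation threshold from the ST reference group
#'
#' tau = mean(ST scores) + k * SD(ST scores), with the sample SD (ddof 1).
#' The default multiplier k = 1.5 defines "c-MET activation" as a signature
#' score more than 1.5 SDs above the surrounding-tissue mean.
#'
#' @param scores Named score vector from [signature_score()].
#' @param clinical Clinical table identifying the `ST` samples.
#' @param k Multiplier on the ST score SD (default 1.5).
#' @return Numeric scalar of class `met_threshold` with attributes
#'   `st_mean`, `st_sd`, `n_st` and `k`.
#' @export
activation_threshold <- function(scores, clinical, k = 1.5) {
  st_ids <- intersect(clinical$sample_id[clinical$sample_type == "ST"],
                      names(scores))
  if (length(st_ids) < 2L)
    stop("need at least 2 ST samples with scores to set the threshold",
         call. = FALSE)
  s <- as.numeric(unclass(scores)[st_ids])
  m <- mean(s)
  sd1 <- stats::sd(s)
  structure(m + k * sd1,
            st_mean = m, st_sd = sd1, n_st = length(st_ids), k = k,
            class = "met_threshold")
}

#' @export
print.met_threshold <- function(x, ...) {
  cat(sprintf(
    "Activation threshold tau = %.6g (ST mean %.6g + %g x ST SD %.6g, n_ST = %d)\n",
    as.numeric(x), attr(x, "st_mean"), attr(x, "k"), attr(x, "st_sd"),
    attr(x, "n_st")))
  invisible(x)
}

#' Call c-MET activation per HCC sample
#'
#' Labels each HCC sample `high` iff its score strictly exceeds `tau`
#' ("more than" the threshold); ties at tau are `low`. ST samples are
#' excluded from the calls.
#'
#' @param scores Named score vector from [signature_score()].
#' @param clinical Clinical table identifying the `HCC` samples.
#' @param tau Activation threshold, typically from
#'   [activation_threshold()].
#' @return Data frame of class `met_activation` with columns `sample_id`,
#'   `score`, `met_class`, and threshold metadata in attributes.
#' @export
classify_met <- function(scores, clinical, tau) {
  tau_val <- as.numeric(tau)
  if (!is.finite(tau_val)) stop("tau must be finite", call. = FALSE)
  hcc <- intersect(clinical$sample_id[clinical$sample_type == "HCC"],
                   names(scores))
  if (!length(hcc))
    stop("no HCC samples with scores to classify", call. = FALSE)
  s <- as.numeric(unclass(scores)[hcc])
  out <- data.frame(sample_id = hcc,
                    score = s,
                    met_class = ifelse(s > tau_val, "high", "low"),
                    stringsAsFactors = FALSE)
  structure(out, tau = tau_val, threshold = tau,
            class = c("met_activation", "data.frame"))
}

#' @export
print.met_activation <- function(x, ...) {
  cat("c-MET activation calls: ", nrow(x), " HCC samples, ",
      sum(x$met_class == "high"), " high / ", sum(x$met_class == "low"),
      " low (tau = ", format(attr(x, "tau"), digits = 6), ")\n", sep = "")
  print.data.frame(utils::head(x, 10), ...)
  if (nrow(x) > 10) cat("... (", nrow(x) - 10, " more rows)\n", sep = "")
  invisible(x)
}
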