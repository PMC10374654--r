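# Readers and writers for the cohort tables the pipeline consumes:
# gene x sample expression (TSV), GMT gene sets, clinical tables (CSV),
# mutation calls (TSV) and per-gene DEG statistic tables (TSV).
# Every reader validates; downstream code operates on checked structures.

#' Canonical variant-class vocabulary
#'
#' The six variant classes recognised in mutation tables. Unknown classes are
#' mapped to `"other"` (with a warning) unless an alias table translates them.
#'
#' @format Character vector of length 6.
#' @export
VARIANT_CLASSES <- c("missense", "truncating", "splice", "inframe",
                     "deletion_null", "other")

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Construct a gene set
#'
#' @param name Set name (non-empty string).
#' @param genes Character vector of unique member gene symbols (non-empty).
#' @return An object of class `gene_set`: a list with elements `name` and
#'   `genes`.
#' @export
gene_set <- function(name, genes) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop("gene set name must be a single non-empty string", call. = FALSE)
  genes <- as.character(genes)
  if (!length(genes))
    stop("gene set '", name, "' has no members", call. = FALSE)
  if (anyDuplicated(genes))
    stop("gene set '", name, "' has duplicate members", call. = FALSE)
  structure(list(name = name, genes = genes), class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat("Gene set '", x$name, "' (", length(x$genes), " genes)\n", sep = "")
  cat(" ", paste(utils::head(x$genes, 10), collapse = ", "),
      if (length(x$genes) > 10) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' Read a gene-by-sample expression matrix from TSV
#'
#' First column holds gene symbols, the header row holds sample ids, the body
#' is numeric. Row and column order are preserved. Duplicate gene or sample
#' labels and non-numeric or non-finite cells are errors; missing values are
#' never imputed.
#'
#' @param path Path to a tab-separated file.
#' @return Numeric matrix with gene rownames and sample colnames.
#' @export
read_expression <- function(path) {
  if (!file.exists(path))
    stop("expression file not found: ", path, call. = FALSE)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, colClasses = "character")
  if (ncol(raw) < 2L)
    stop("expression file needs a gene column plus at least one sample column",
         call. = FALSE)
  genes <- raw[[1L]]
  samples <- colnames(raw)[-1L]
  dup <- unique(genes[duplicated(genes)])
  if (length(dup))
    stop("duplicate gene symbol(s) in expression file: ",
         paste(dup, collapse = ", "), call. = FALSE)
  dup <- unique(samples[duplicated(samples)])
  if (length(dup))
    stop("duplicate sample id(s) in expression file: ",
         paste(dup, collapse = ", "), call. = FALSE)
  body <- as.matrix(raw[, -1L, drop = FALSE])
  vals <- suppressWarnings(array(as.numeric(body), dim = dim(body)))
  bad <- which(!is.finite(vals), arr.ind = TRUE)
  if (nrow(bad)) {
    i <- bad[1L, 1L]; j <- bad[1L, 2L]
    stop(sprintf(
      "non-numeric or non-finite expression value '%s' at gene '%s', sample '%s'",
      body[i, j], genes[i], samples[j]), call. = FALSE)
  }
  dimnames(vals) <- list(genes, samples)
  vals
}

#' Write an expression matrix as TSV
#'
#' Inverse of [read_expression()]: gene symbols in the first column
#' (`gene`), one column per sample.
#'
#' @param expr Numeric matrix with gene rownames and sample colnames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path) {
  stopifnot(is.matrix(expr), !is.null(rownames(expr)), !is.null(colnames(expr)))
  df <- data.frame(gene = rownames(expr), expr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' Standard GMT dialect: one set per line, tab-separated fields
#' `name`, `description`, then member symbols. The description is discarded;
#' duplicate members within a line are removed with a warning.
#'
#' @param path Path to a GMT file.
#' @return Named list of [gene_set()] objects.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty GMT file: ", path, call. = FALSE)
  sets <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L)
      stop(sprintf(
        "GMT format error at line %d: %d field(s); need name, description and at least one member",
        i, length(f)), call. = FALSE)
    name <- f[1L]
    members <- f[-c(1L, 2L)]
    members <- members[nzchar(members)]
    if (anyDuplicated(members)) {
      warning("GMT set '", name, "': duplicate members removed", call. = FALSE)
      members <- unique(members)
    }
    if (!length(members))
      stop(sprintf("GMT format error at line %d: set '%s' has no members",
                   i, name), call. = FALSE)
    sets[[i]] <- gene_set(name, members)
  }
  names(sets) <- vapply(sets, function(s) s$name, character(1))
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets A [gene_set()] or list of them.
#' @param path Output path.
#' @param description Description field written for every set (GMT column 2).
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, description = "na") {
  if (inherits(sets, "gene_set")) sets <- list(sets)
  lines <- vapply(sets, function(s)
    paste(c(s$name, description, s$genes), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a clinical table from CSV
#'
#' Requires columns `sample_id`, `sample_type` (one of `HCC`, `ST`),
#' `os_time` (overall-survival time, >= 0) and `os_event` (1 = death
#' observed, 0 = censored).
#'
#' @param path Path to a CSV file.
#' @return Validated data frame.
#' @export
read_clinical <- function(path) {
  if (!file.exists(path)) stop("clinical file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  req <- c("sample_id", "sample_type", "os_time", "os_event")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("clinical table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  validate_clinical(df)
}

#' Validate a clinical table
#'
#' @param df Data frame with the columns of [read_clinical()].
#' @return The validated data frame (numeric `os_time`, integer `os_event`).
#' @export
validate_clinical <- function(df) {
  bad <- setdiff(unique(as.character(df$sample_type)), c("HCC", "ST"))
  if (length(bad))
    stop("unknown sample_type label(s): ", paste(bad, collapse = ", "),
         " (allowed: HCC, ST)", call. = FALSE)
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id in clinical table", call. = FALSE)
  os_time <- suppressWarnings(as.numeric(df$os_time))
  if (anyNA(os_time) || any(os_time < 0))
    stop("os_time must be numeric and >= 0", call. = FALSE)
  os_event <- suppressWarnings(as.integer(df$os_event))
  if (anyNA(os_event) || !all(os_event %in% c(0L, 1L)))
    stop("os_event must be 0 or 1", call. = FALSE)
  df$os_time <- os_time
  df$os_event <- os_event
  df
}

#' Write a clinical table as CSV
#'
#' @param clinical Data frame as returned by [read_clinical()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_clinical <- function(clinical, path) {
  utils::write.csv(clinical, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read mutation calls from TSV
#'
#' Requires columns `sample_id`, `gene`, `variant_class`. Classes outside
#' [VARIANT_CLASSES] are first translated through the optional `aliases`
#' table (e.g. MAF `Nonsense_Mutation` -> `truncating`); anything still
#' unknown is mapped to `"other"` with a warning. Duplicate
#' (sample, gene, class) records are collapsed with a warning.
#'
#' @param path Path to a tab-separated file.
#' @param aliases Optional named character vector mapping foreign class
#'   labels to canonical ones.
#' @return Validated data frame with canonical `variant_class`.
#' @export
read_mutations <- function(path, aliases = NULL) {
  if (!file.exists(path)) stop("mutation file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  req <- c("sample_id", "gene", "variant_class")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("mutation table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  vc <- as.character(df$variant_class)
  if (!is.null(aliases)) {
    hit <- vc %in% names(aliases)
    vc[hit] <- unname(aliases[vc[hit]])
  }
  unknown <- setdiff(unique(vc), VARIANT_CLASSES)
  if (length(unknown)) {
    warning("unknown variant class(es) mapped to 'other': ",
            paste(unknown, collapse = ", "), call. = FALSE)
    vc[vc %in% unknown] <- "other"
  }
  df$variant_class <- vc
  dup <- duplicated(df[, req])
  if (any(dup)) {
    warning(sum(dup), " duplicate (sample, gene, class) record(s) collapsed",
            call. = FALSE)
    df <- df[!dup, , drop = FALSE]
    rownames(df) <- NULL
  }
  df
}

#' Write mutation calls as TSV
#'
#' @param mutations Data frame as returned by [read_mutations()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mutations <- function(mutations, path) {
  utils::write.table(mutations, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a per-gene DEG statistic table from TSV
#'
#' Requires columns `gene`, `p_value`, and either `fold_change` (linear,
#' ratio scale) or `log2_fold_change`; a log2 column is converted to linear
#' internally. An optional `p_adj` column is kept; when absent downstream
#' filtering computes it with [bh_adjust()].
#'
#' @param path Path to a tab-separated file.
#' @param log2 Force interpretation of the fold-change column as log2
#'   (`TRUE`), linear (`FALSE`), or decide from the column name (`NULL`,
#'   default).
#' @return Validated data frame with columns `gene`, `fold_change` (linear),
#'   `p_value` and, when present, `p_adj`.
#' @export
read_deg_table <- function(path, log2 = NULL) {
  if (!file.exists(path)) stop("DEG table not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"gene" %in% names(df))
    stop("DEG table missing 'gene' column", call. = FALSE)
  has_lin <- "fold_change" %in% names(df)
  has_log <- "log2_fold_change" %in% names(df)
  if (!has_lin && !has_log)
    stop("DEG table needs a 'fold_change' or 'log2_fold_change' column",
         call. = FALSE)
  if (is.null(log2)) log2 <- has_log && !has_lin
  fc <- as.numeric(if (has_log && (log2 || !has_lin)) df$log2_fold_change
                   else df$fold_change)
  if (log2) fc <- 2^fc
  if (!"p_value" %in% names(df))
    stop("DEG table missing 'p_value' column", call. = FALSE)
  p <- as.numeric(df$p_value)
  if (anyNA(fc) || any(fc <= 0))
    stop("fold_change must be a positive ratio", call. = FALSE)
  if (anyNA(p) || any(p < 0 | p > 1))
    stop("p_value must lie in [0, 1]", call. = FALSE)
  if (anyDuplicated(df$gene))
    stop("duplicate gene symbols in DEG table", call. = FALSE)
  out <- data.frame(gene = as.character(df$gene), fold_change = fc,
                    p_value = p, stringsAsFactors = FALSE)
  if ("p_adj" %in% names(df)) {
    pa <- as.numeric(df$p_adj)
    if (anyNA(pa) || any(pa < 0 | pa > 1))
      stop("p_adj must lie in [0, 1]", call. = FALSE)
    out$p_adj <- pa
  }
  out
}

#' Write a DEG statistic table as TSV
#'
#' @param table Data frame with columns `gene`, `fold_change`, `p_value`
#'   and optionally `p_adj`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_deg_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
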