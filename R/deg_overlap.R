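# DEG filtering (fold change > 1.5, adjusted p < 0.05), mouse-to-human
# symbol mapping, cross-species overlap counts, and hypergeometric
# over-representation of gene-set categories in a hit list.

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment (monotone, capped at 1, input order preserved).
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values in input order.
#' @export
bh_adjust <- function(p) {
  p <- as.numeric(p)
  if (!length(p)) stop("no p-values to adjust", call. = FALSE)
  if (anyNA(p) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(p, method = "BH")
}

#' Filter a DEG table
#'
#' Retains genes whose fold change strictly exceeds `fc_cutoff` (direction
#' `"up"`; strictly below `1/fc_cutoff` for `"down"`; either for `"both"`)
#' and whose adjusted p is strictly below `padj_cutoff`. When the table has
#' no `p_adj` column it is computed with [bh_adjust()] first. An optional
#' raw-p gate (`p_cutoff`) can be added on top; by default only the
#' adjusted-p gate applies.
#'
#' @param table DEG data frame with columns `gene`, `fold_change` (linear),
#'   `p_value` and optionally `p_adj`.
#' @param fc_cutoff Linear fold-change cutoff (> 0, default 1.5).
#' @param padj_cutoff Adjusted-p cutoff (in (0, 1\], default 0.05).
#' @param direction `"up"` (default), `"down"` or `"both"`.
#' @param p_cutoff Optional raw p-value gate (default `NULL`, off).
#' @return Character vector of retained gene symbols in input order.
#' @export
filter_degs <- function(table, fc_cutoff = 1.5, padj_cutoff = 0.05,
                        direction = c("up", "down", "both"), p_cutoff = NULL) {
  direction <- match.arg(direction)
  if (is.null(table) || !nrow(table)) stop("empty DEG table", call. = FALSE)
  stopifnot(fc_cutoff > 0, padj_cutoff > 0, padj_cutoff <= 1)
  req <- c("gene", "fold_change", "p_value")
  miss <- setdiff(req, names(table))
  if (length(miss))
    stop("DEG table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (is.null(table$p_adj)) table$p_adj <- bh_adjust(table$p_value)
  fc <- table$fold_change
  dir_ok <- switch(direction,
                   up = fc > fc_cutoff,
                   down = fc < 1 / fc_cutoff,
                   both = fc > fc_cutoff | fc < 1 / fc_cutoff)
  keep <- dir_ok & table$p_adj < padj_cutoff
  if (!is.null(p_cutoff)) keep <- keep & table$p_value < p_cutoff
  as.character(table$gene[keep])
}

# Mouse symbols whose human ortholog is not the uppercased symbol.
MOUSE_HUMAN_EXCEPTIONS <- c(Trp53 = "TP53", Trp63 = "TP63", Trp73 = "TP73")

#' Map mouse gene symbols to human
#'
#' With a supplied mapping table the translation is a lookup and symbols
#' absent from the table are reported as unmapped (never silently dropped).
#' Without one, the default rule uppercases each symbol, with a built-in
#' exception list for known non-trivial pairs (e.g. `Trp53` -> `TP53`).
#'
#' @param symbols Character vector of mouse symbols (non-empty).
#' @param mapping Optional mapping: a named character vector
#'   (mouse -> human) or a two-column data frame (mouse, human).
#' @return List with `mapped` (named character vector, names = input
#'   symbols) and `unmapped` (character vector).
#' @export
map_orthologs <- function(symbols, mapping = NULL) {
  if (!length(symbols)) stop("no symbols to map", call. = FALSE)
  symbols <- as.character(symbols)
  if (is.null(mapping)) {
    mapped <- toupper(symbols)
    exc <- symbols %in% names(MOUSE_HUMAN_EXCEPTIONS)
    mapped[exc] <- unname(MOUSE_HUMAN_EXCEPTIONS[symbols[exc]])
    names(mapped) <- symbols
    unmapped <- character(0)
  } else {
    if (is.data.frame(mapping)) {
      if (ncol(mapping) < 2L)
        stop("mapping data frame needs two columns (mouse, human)",
             call. = FALSE)
      mapping <- stats::setNames(as.character(mapping[[2L]]),
                                 as.character(mapping[[1L]]))
    }
    hit <- symbols %in% names(mapping)
    mapped <- stats::setNames(unname(mapping[symbols[hit]]), symbols[hit])
    unmapped <- symbols[!hit]
  }
  list(mapped = mapped, unmapped = unmapped)
}

#' Overlap of two gene lists
#'
#' Exact set algebra between two gene lists (duplicates removed), the
#' skeleton of a two-set Venn diagram.
#'
#' @param a,b Character vectors of gene symbols.
#' @param universe Optional universe for context (size recorded only).
#' @return Object of class `overlap_result`: list with `n_a`, `n_b`,
#'   `n_intersection`, `n_union`, `n_a_only`, `n_b_only`, `n_universe`,
#'   and the `intersection` genes.
#' @export
overlap <- function(a, b, universe = NULL) {
  a <- unique(as.character(a)); b <- unique(as.character(b))
  int <- intersect(a, b)
  structure(list(n_a = length(a), n_b = length(b),
                 n_intersection = length(int),
                 n_union = length(union(a, b)),
                 n_a_only = length(setdiff(a, b)),
                 n_b_only = length(setdiff(b, a)),
                 n_universe = if (is.null(universe)) NA_integer_
                              else length(unique(universe)),
                 intersection = int),
            class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf(
    "Overlap: |A| = %d, |B| = %d, |A n B| = %d, |A u B| = %d (A only %d, B only %d)\n",
    x$n_a, x$n_b, x$n_intersection, x$n_union, x$n_a_only, x$n_b_only))
  invisible(x)
}

#' Over-representation test (hypergeometric)
#'
#' Upper-tail hypergeometric p-value of each category's overlap with the
#' hit list, drawn without replacement from the universe. Categories are
#' intersected with the universe before testing; fold enrichment is
#' (overlap/hits) / (category/universe); p-values are BH-adjusted across
#' categories.
#'
#' @param hits Character vector of hit genes (non-empty, subset of
#'   `universe`).
#' @param categories A [gene_set()], list of gene sets, or named list of
#'   character vectors.
#' @param universe Character vector of background genes (non-empty).
#' @return Data frame with one row per category: `category`, `n_category`,
#'   `n_overlap`, `n_hits`, `n_universe`, `fold_enrichment`, `p_value`,
#'   `p_adj`.
#' @export
ora_test <- function(hits, categories, universe) {
  hits <- unique(as.character(hits))
  universe <- unique(as.character(universe))
  if (!length(universe)) stop("empty universe", call. = FALSE)
  if (!length(hits)) stop("empty hit list", call. = FALSE)
  stray <- setdiff(hits, universe)
  if (length(stray))
    stop("hit gene(s) outside the universe: ",
         paste(utils::head(stray, 5), collapse = ", "), call. = FALSE)
  if (inherits(categories, "gene_set")) categories <- list(categories)
  N <- length(universe)
  n <- length(hits)
  rows <- lapply(seq_along(categories), function(i) {
    cat_i <- categories[[i]]
    nm <- if (inherits(cat_i, "gene_set")) cat_i$name
          else names(categories)[i] %||% paste0("category_", i)
    genes <- if (inherits(cat_i, "gene_set")) cat_i$genes
             else as.character(cat_i)
    K <- length(intersect(genes, universe))
    k <- length(intersect(genes, hits))
    p <- if (K == 0L) 1 else stats::phyper(k - 1, K, N - K, n,
                                           lower.tail = FALSE)
    fe <- if (K == 0L) NA_real_ else (k / n) / (K / N)
    data.frame(category = nm, n_category = K, n_overlap = k,
               n_hits = n, n_universe = N, fold_enrichment = fe,
               p_value = p, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$p_adj <- bh_adjust(res$p_value)
  res
}
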