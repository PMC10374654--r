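# File-level orchestration: validate a run configuration, execute the
# co-occurrence or overlap pipeline on files, write every stage output as
# TSV/JSON and a machine-readable manifest with checksums, collected
# warnings and timing.

stop_validation <- function(...) {
  stop(structure(class = c("met53_validation_error", "error", "condition"),
                 list(message = paste0(...), call = NULL)))
}

resolve_config <- function(config, defaults, required) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config))
      stop_validation("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  cfg <- utils::modifyList(defaults, as.list(config))
  miss <- required[vapply(cfg[required], is.null, logical(1))]
  if (length(miss))
    stop_validation("config missing required field(s): ",
                    paste(miss, collapse = ", "))
  for (f in required) {
    if (grepl("_path$|^expression$|^clinical$|^mutations$|^gmt$|^table_",
              f) && is.character(cfg[[f]]) && !file.exists(cfg[[f]]))
      stop_validation("input file for '", f, "' not found: ", cfg[[f]])
  }
  cfg
}

manifest_checksums <- function(paths) {
  paths <- paths[file.exists(paths)]
  as.list(tools::md5sum(paths))
}

write_run_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Run the co-occurrence pipeline on files
#'
#' Executes score -> threshold -> classify -> stratify -> crosstab ->
#' score comparison -> KM / log-rank from a declarative configuration
#' (a list or the path to a YAML file) and writes every stage output plus
#' a manifest (config echo, package version, input/output checksums,
#' collected warnings, timing) under `out_dir`.
#'
#' Required config fields: `expression`, `clinical`, `mutations`, `gmt`
#' and `out_dir`. Optional: `set_name` (default: first GMT set), `k`
#' (1.5), `reference` (`"all"`), `null_definition`, `min_genes`,
#' `contrast` (`"double_vs_rest"`).
#'
#' @param config Named list or YAML path.
#' @return Invisibly, a list with the fitted [met_cooccurrence()] `result`
#'   and the `manifest`.
#' @export
run_cooccurrence <- function(config) {
  defaults <- list(set_name = NULL, k = 1.5, reference = "all",
                   null_definition = c("truncating", "splice",
                                       "deletion_null"),
                   min_genes = NULL, contrast = "double_vs_rest")
  cfg <- resolve_config(config, defaults,
                        c("expression", "clinical", "mutations", "gmt",
                          "out_dir"))
  cfg$null_definition <- unlist(cfg$null_definition)
  warns <- character(0)
  t0 <- Sys.time()
  res <- withCallingHandlers({
    expr <- read_expression(cfg$expression)
    clinical <- read_clinical(cfg$clinical)
    mutations <- read_mutations(cfg$mutations)
    sets <- read_gmt(cfg$gmt)
    set <- if (is.null(cfg$set_name)) sets[[1L]] else sets[[cfg$set_name]]
    if (is.null(set))
      stop_validation("gene set '", cfg$set_name, "' not found in ", cfg$gmt)
    cfg$set_name <- set$name
    met_cooccurrence(expr, clinical, mutations, set, k = cfg$k,
                     reference = cfg$reference,
                     null_definition = cfg$null_definition,
                     min_genes = cfg$min_genes, contrast = cfg$contrast)
  }, warning = function(w) {
    warns <<- c(warns, conditionMessage(w))
    invokeRestart("muffleWarning")
  })

  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(cfg$out_dir, f)
  utils::write.table(
    data.frame(sample_id = res$activation$sample_id,
               score = res$activation$score,
               class = res$activation$met_class),
    out("scores.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  write_run_json(list(tau = attr(res$activation, "tau"),
                      k = attr(res$threshold, "k"),
                      st_mean = attr(res$threshold, "st_mean"),
                      st_sd = attr(res$threshold, "st_sd"),
                      n_st = attr(res$threshold, "n_st"),
                      dropped_genes = as.list(attr(res$scores,
                                                   "missing_genes"))),
                 out("threshold.json"))
  utils::write.table(as.data.frame(res$strata), out("strata.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  xt <- res$crosstab
  utils::write.table(
    data.frame(tp53 = rep(rownames(xt$counts), 2),
               met = rep(colnames(xt$counts), each = 2),
               count = as.vector(xt$counts),
               row_proportion = as.vector(xt$row_proportions)),
    out("crosstab.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  for (s in names(res$km))
    utils::write.table(as.data.frame(res$km[[s]]),
                       out(paste0("km_", s, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(res$logrank))
    write_run_json(list(statistic = res$logrank$statistic,
                        df = res$logrank$df,
                        p_value = res$logrank$p_value,
                        observed = as.list(res$logrank$observed),
                        expected = as.list(res$logrank$expected)),
                   out("logrank.json"))

  outputs <- list.files(cfg$out_dir, full.names = TRUE)
  outputs <- outputs[basename(outputs) != "manifest.json"]
  manifest <- list(
    package = "met53",
    version = as.character(utils::packageVersion("met53")),
    pipeline = "cooccurrence",
    config = cfg,
    inputs = manifest_checksums(c(cfg$expression, cfg$clinical,
                                  cfg$mutations, cfg$gmt)),
    outputs = manifest_checksums(outputs),
    warnings = as.list(warns),
    timing_sec = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  write_run_json(manifest, out("manifest.json"))
  invisible(list(result = res, manifest = manifest))
}

#' Run the cross-species DEG overlap pipeline on files
#'
#' Executes BH adjustment -> DEG filtering on two statistic tables (table
#' A is treated as the mouse table and symbol-mapped to human), computes
#' the overlap, and, when a GMT of categories is supplied, an
#' over-representation test of the overlapping genes against the table-B
#' universe. Writes Venn counts, gene lists, the enrichment table and a
#' manifest under `out_dir`.
#'
#' Required config fields: `table_a`, `table_b`, `out_dir`. Optional:
#' `fc_cutoff` (1.5), `padj_cutoff` (0.05), `direction` (`"up"`),
#' `p_cutoff` (off), `log2_a`/`log2_b` (auto), `mapping` (path to a
#' two-column TSV, default built-in rule), `gmt`, `universe` (path to a
#' one-symbol-per-line list, default: all table-B genes).
#'
#' @param config Named list or YAML path.
#' @return Invisibly, a list with `filtered_a`, `filtered_b`,
#'   `mapped_a`, `overlap`, `enrichment` (or `NULL`) and the `manifest`.
#' @export
run_overlap <- function(config) {
  defaults <- list(fc_cutoff = 1.5, padj_cutoff = 0.05, direction = "up",
                   p_cutoff = NULL, log2_a = NULL, log2_b = NULL,
                   mapping = NULL, gmt = NULL, universe = NULL)
  cfg <- resolve_config(config, defaults, c("table_a", "table_b", "out_dir"))
  warns <- character(0)
  t0 <- Sys.time()
  res <- withCallingHandlers({
    ta <- read_deg_table(cfg$table_a, log2 = cfg$log2_a)
    tb <- read_deg_table(cfg$table_b, log2 = cfg$log2_b)
    fa <- filter_degs(ta, cfg$fc_cutoff, cfg$padj_cutoff, cfg$direction,
                      cfg$p_cutoff)
    fb <- filter_degs(tb, cfg$fc_cutoff, cfg$padj_cutoff, cfg$direction,
                      cfg$p_cutoff)
    mapping <- if (!is.null(cfg$mapping))
      utils::read.delim(cfg$mapping, stringsAsFactors = FALSE)
    else NULL
    mapped <- if (length(fa)) map_orthologs(fa, mapping)
              else list(mapped = character(0), unmapped = character(0))
    if (length(mapped$unmapped))
      warning(length(mapped$unmapped), " symbol(s) unmapped", call. = FALSE)
    universe <- if (!is.null(cfg$universe)) readLines(cfg$universe)
                else tb$gene
    ov <- overlap(mapped$mapped, fb, universe = universe)
    enr <- NULL
    if (!is.null(cfg$gmt)) {
      hits <- intersect(ov$intersection, universe)
      if (!length(hits)) {
        warning("empty post-filter overlap; enrichment skipped",
                call. = FALSE)
      } else {
        enr <- ora_test(hits, read_gmt(cfg$gmt), universe)
      }
    }
    list(filtered_a = fa, filtered_b = fb, mapped_a = mapped,
         overlap = ov, enrichment = enr)
  }, warning = function(w) {
    warns <<- c(warns, conditionMessage(w))
    invokeRestart("muffleWarning")
  })

  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(cfg$out_dir, f)
  writeLines(res$mapped_a$mapped, out("genes_a_mapped.txt"))
  writeLines(res$filtered_b, out("genes_b.txt"))
  writeLines(res$overlap$intersection, out("genes_overlap.txt"))
  ov <- res$overlap
  write_run_json(list(n_a = ov$n_a, n_b = ov$n_b,
                      n_intersection = ov$n_intersection,
                      n_union = ov$n_union, n_a_only = ov$n_a_only,
                      n_b_only = ov$n_b_only, n_universe = ov$n_universe,
                      n_unmapped = length(res$mapped_a$unmapped)),
                 out("venn.json"))
  if (!is.null(res$enrichment))
    utils::write.table(res$enrichment, out("enrichment.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)

  outputs <- list.files(cfg$out_dir, full.names = TRUE)
  outputs <- outputs[basename(outputs) != "manifest.json"]
  manifest <- list(
    package = "met53",
    version = as.character(utils::packageVersion("met53")),
    pipeline = "overlap",
    config = cfg,
    inputs = manifest_checksums(c(cfg$table_a, cfg$table_b,
                                  cfg$mapping %||% character(0),
                                  cfg$gmt %||% character(0))),
    outputs = manifest_checksums(outputs),
    warnings = as.list(warns),
    timing_sec = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  write_run_json(manifest, out("manifest.json"))
  invisible(c(res, list(manifest = manifest)))
}
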