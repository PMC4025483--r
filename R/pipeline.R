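# End-to-end pipeline drivers: read inputs, run every stage, write a report
# bundle (TSV/JSON artifacts plus a deterministic run log) into an output
# directory. The config is a plain named list, or a path to a YAML file with
# the same keys.

load_pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) {
      abort(sprintf("Config file '%s' does not exist.", config))
    }
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) abort("`config` must be a named list or a YAML path.")
  config
}

config_get <- function(config, key, default = NULL, required = FALSE) {
  if (!is.null(config[[key]])) return(config[[key]])
  if (required) abort(sprintf("Config key '%s' is required.", key))
  default
}

write_run_log <- function(path, pipeline, params) {
  lines <- c(
    sprintf("pipeline: %s", pipeline),
    sprintf("eigenmetab version: %s", as.character(packageVersion("eigenmetab"))),
    sprintf("R version: %s.%s", R.version$major, R.version$minor),
    "parameters:",
    vapply(names(params), function(k) {
      sprintf("  %s: %s", k, paste(format(params[[k]]), collapse = ", "))
    }, character(1))
  )
  writeLines(lines, path)
}

#' Run the eigengene analysis pipeline
#'
#' Reads an expression table, decomposes it into eigengenes, writes the
#' eigengene patterns, eigenexpression fractions and entropy, the top-N
#' ranked gene list for each requested pattern, and — when an annotation
#' catalog is supplied — the hypergeometric enrichment of each ranked list.
#'
#' @param config Named list or YAML path with keys:
#'   \describe{
#'     \item{expression}{path to an expression table, or a data frame (required).}
#'     \item{out_dir}{output directory, created if absent (required).}
#'     \item{catalog}{path to a gene-list file, or an [annotation_catalog()] (optional).}
#'     \item{patterns}{pattern indices to rank (default `1:3`).}
#'     \item{top_n}{ranked-list size (default 500, capped checks run before compute).}
#'     \item{transform}{`"none"` or `"log1p"` (default `"none"`).}
#'     \item{center}{logical (default `FALSE`).}
#'     \item{seed}{recorded in the log (default 1; the decomposition itself is deterministic).}
#'   }
#' @return Invisibly, a list with `fit`, `ranked` (list of tibbles),
#'   `enrichment` (tibble or `NULL`), and `files` (paths written).
#' @export
#' @examples
#' sim <- simulate_expression(n_genes = 300, n_timepoints = 6, seed = 1)
#' out <- run_eigengene_pipeline(list(
#'   expression = sim$expression,
#'   out_dir = tempfile("eig"),
#'   patterns = 1:2, top_n = 50
#' ))
#' glance(out$fit)
run_eigengene_pipeline <- function(config) {
  config <- load_pipeline_config(config)
  out_dir <- config_get(config, "out_dir", required = TRUE)
  expression <- config_get(config, "expression", required = TRUE)
  if (is.character(expression)) {
    expression <- read_expression_matrix(expression)
  } else {
    expression <- as_expression_matrix(expression)
  }
  patterns <- config_get(config, "patterns", default = 1:3)
  top_n <- check_count(config_get(config, "top_n", default = 500),
                       "top_n", min = 1L)
  transform <- config_get(config, "transform", default = "none")
  center <- isTRUE(config_get(config, "center", default = FALSE))
  seed <- config_get(config, "seed", default = 1)

  # validate before any compute
  n_genes <- nrow(expression)
  n_tp <- ncol(expression) - 1L
  if (top_n > n_genes) {
    abort(sprintf("`top_n` (%d) exceeds the gene count (%d).", top_n, n_genes))
  }
  bad <- setdiff(patterns, seq_len(n_tp))
  if (length(bad) > 0L) {
    abort(sprintf(
      "Requested pattern(s) out of range: %s (only %d timepoints).",
      paste(bad, collapse = ", "), n_tp
    ))
  }
  catalog <- config_get(config, "catalog")
  if (is.character(catalog)) {
    catalog <- read_annotation_catalog(catalog, universe = expression$gene_id)
  }

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)

  fit <- eigen_decompose(expression, transform = transform, center = center)

  f <- file.path(out_dir, "eigengenes.tsv")
  readr::write_tsv(as_tibble(fit$eigengenes, rownames = "pattern"), f)
  files <- c(files, f)

  f <- file.path(out_dir, "fractions_entropy.json")
  jsonlite::write_json(
    list(
      singular_values = fit$singular_values,
      fractions = fit$fractions,
      cumulative = cumsum(fit$fractions),
      entropy = fit$entropy
    ),
    f, digits = NA, auto_unbox = FALSE
  )
  files <- c(files, f)

  ranked <- list()
  enr_rows <- list()
  for (p in patterns) {
    rl <- rank_genes(fit, pattern = p, top_n = top_n)
    ranked[[as.character(p)]] <- rl
    f <- file.path(out_dir, sprintf("ranked_pattern%d.tsv", p))
    readr::write_tsv(rl, f)
    files <- c(files, f)
    if (!is.null(catalog)) {
      enr_rows[[as.character(p)]] <- enrich(rl, catalog) %>%
        mutate(pattern = p, .before = 1L)
    }
  }

  enrichment <- NULL
  if (length(enr_rows) > 0L) {
    enrichment <- bind_rows(enr_rows)
    f <- file.path(out_dir, "enrichment.tsv")
    readr::write_tsv(enrichment, f)
    files <- c(files, f)
    f <- file.path(out_dir, "enrichment.json")
    jsonlite::write_json(enrichment, f, digits = NA)
    files <- c(files, f)
  }

  f <- file.path(out_dir, "run_log.txt")
  write_run_log(f, "eigengene", list(
    n_genes = n_genes, n_timepoints = n_tp, patterns = patterns,
    top_n = top_n, transform = transform, center = center, seed = seed,
    catalog = if (is.null(catalog)) "none" else catalog$label
  ))
  files <- c(files, f)

  invisible(list(fit = fit, ranked = ranked, enrichment = enrichment,
                 files = files))
}

#' Run the metabolite time-course pipeline
#'
#' Reads a peak-area table, normalizes to the internal standard, rescales
#' relative to the baseline stage, writes the per-timepoint summary table, a
#' JSON report of significant changes, requested metabolite-ratio series,
#' and — when a store assay is supplied — the nutrient-store statistics.
#'
#' @param config Named list or YAML path with keys:
#'   \describe{
#'     \item{peaks}{path to a peak table, or a long-format tibble (required).}
#'     \item{out_dir}{output directory (required).}
#'     \item{format}{`"long"` or `"wide"` when `peaks` is a path (default `"long"`).}
#'     \item{standard}{internal-standard name (default `"D4-succinate"`).}
#'     \item{baseline}{baseline stage label (default: first timepoint level).}
#'     \item{alpha}{metabolite significance threshold (default 0.01).}
#'     \item{ratios}{list of 2-vectors `c(numerator, denominator)` (optional).}
#'     \item{stores}{path to a store-assay table, or a tibble (optional).}
#'     \item{store_alpha}{store significance threshold (default 0.05).}
#'     \item{figures}{if `TRUE`, also write box-plot / store figures as PDF (default `FALSE`).}
#'   }
#' @return Invisibly, a list with `summary`, `ratios` (named list of
#'   tibbles), `stores` (tibble or `NULL`), and `files`.
#' @export
run_metabolome_pipeline <- function(config) {
  config <- load_pipeline_config(config)
  out_dir <- config_get(config, "out_dir", required = TRUE)
  peaks <- config_get(config, "peaks", required = TRUE)
  if (is.character(peaks)) {
    peaks <- read_metabolite_table(
      peaks,
      format = config_get(config, "format", default = "long")
    )
  }
  require_columns(peaks, c("sample_id", "timepoint", "replicate",
                           "metabolite", "peak_area"), "`peaks`")
  standard <- config_get(config, "standard", default = "D4-succinate")
  baseline <- config_get(config, "baseline",
                         default = timepoint_levels(peaks$timepoint)[1L])
  alpha <- config_get(config, "alpha", default = 0.01)

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)

  normalized <- normalize_to_standard(peaks, standard = standard)
  rescaled <- relative_to_baseline(normalized, baseline = baseline)
  summary <- summarize_timecourse(rescaled, baseline = baseline, alpha = alpha)

  f <- file.path(out_dir, "metabolite_summary.tsv")
  readr::write_tsv(summary, f)
  files <- c(files, f)

  sig <- summary %>% filter(.data$significant)
  f <- file.path(out_dir, "significant_changes.json")
  jsonlite::write_json(
    list(
      baseline = baseline, alpha = alpha,
      n_tests = sum(!is.na(summary$p_value)),
      significant = sig %>%
        select("metabolite", "timepoint", "median", "p_value") %>%
        mutate(timepoint = as.character(.data$timepoint))
    ),
    f, digits = NA, auto_unbox = TRUE
  )
  files <- c(files, f)

  ratios <- list()
  for (pair in config_get(config, "ratios", default = list())) {
    rs <- ratio_series(normalized, pair[[1L]], pair[[2L]])
    key <- sprintf("%s_over_%s", pair[[1L]], pair[[2L]])
    ratios[[key]] <- rs
    f <- file.path(out_dir, sprintf("ratio_%s.tsv", key))
    readr::write_tsv(rs, f)
    files <- c(files, f)
  }

  stores <- NULL
  store_input <- config_get(config, "stores")
  if (!is.null(store_input)) {
    if (is.character(store_input)) store_input <- read_store_assay(store_input)
    stores <- analyze_stores(
      store_input,
      alpha = config_get(config, "store_alpha", default = 0.05)
    )
    f <- file.path(out_dir, "store_summary.tsv")
    readr::write_tsv(stores, f)
    files <- c(files, f)
  }

  if (isTRUE(config_get(config, "figures", default = FALSE))) {
    f <- file.path(out_dir, "metabolite_boxes.pdf")
    ggplot2::ggsave(f, plot_metabolite_boxes(summary),
                    width = 10, height = 8)
    files <- c(files, f)
    if (!is.null(stores)) {
      f <- file.path(out_dir, "store_series.pdf")
      ggplot2::ggsave(f, plot_store_series(stores), width = 8, height = 5)
      files <- c(files, f)
    }
  }

  f <- file.path(out_dir, "run_log.txt")
  write_run_log(f, "metabolome", list(
    n_metabolites = length(unique(normalized$metabolite)),
    n_samples = length(unique(normalized$sample_id)),
    standard = standard, baseline = baseline, alpha = alpha
  ))
  files <- c(files, f)

  invisible(list(summary = summary, ratios = ratios, stores = stores,
                 files = files))
}
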