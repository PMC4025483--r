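#' Read a metabolite peak-area table
#'
#' Two dialects are supported. *Long*: one row per sample x metabolite with
#' columns `sample_id`, `timepoint`, `replicate`, `metabolite`, `peak_area`
#' (the internal standard appearing as a metabolite). *Wide*: one row per
#' sample with columns `sample_id`, `timepoint`, `replicate`, one column per
#' metabolite, and a reserved internal-standard column; wide input is pivoted
#' to long. Empty cells become `NA` (below detection — distinct from a
#' measured zero).
#'
#' @param path TSV path (CSV if the extension is `.csv`).
#' @param format `"long"` (default) or `"wide"`.
#' @param timepoint_order Optional character vector fixing stage order;
#'   defaults to order of first appearance.
#' @return A long-format tibble with `timepoint` as an ordered factor.
#' @export
read_metabolite_table <- function(path, format = c("long", "wide"),
                                  timepoint_order = NULL) {
  format <- arg_match(format)
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  data <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                            progress = FALSE)
  require_columns(data, c("sample_id", "timepoint", "replicate"),
                  sprintf("'%s'", path))
  if (format == "wide") {
    data <- data %>%
      tidyr::pivot_longer(
        -c("sample_id", "timepoint", "replicate"),
        names_to = "metabolite", values_to = "peak_area"
      )
  } else {
    require_columns(data, c("metabolite", "peak_area"), sprintf("'%s'", path))
  }
  order <- timepoint_order %||% unique(as.character(data$timepoint))
  data %>%
    mutate(
      timepoint = factor(as.character(.data$timepoint), levels = order),
      peak_area = as.numeric(.data$peak_area)
    )
}

#' Read a nutrient-store assay table
#'
#' @param path TSV with columns `analyte`, `timepoint`, `replicate`, `value`.
#' @param timepoint_order Optional stage order (default: first appearance).
#' @return A tibble with `timepoint` as an ordered factor.
#' @export
read_store_assay <- function(path, timepoint_order = NULL) {
  data <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  require_columns(data, c("analyte", "timepoint", "replicate", "value"),
                  sprintf("'%s'", path))
  order <- timepoint_order %||% unique(as.character(data$timepoint))
  data %>%
    mutate(timepoint = factor(as.character(.data$timepoint), levels = order))
}
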