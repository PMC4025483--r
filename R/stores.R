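#' Nutrient-store assay statistics
#'
#' Summarizes bulk assays of maternally deposited energy stores (triglyceride,
#' glycogen, soluble protein) measured on replicate pools of staged embryos.
#' Each analyte is normalized to the mean of the baseline (earliest) timepoint
#' so the baseline mean is exactly `scale` (1 by default, i.e. fold of
#' baseline); every later timepoint is compared to baseline with a classic
#' pooled-variance Student t-test.
#'
#' @param assay Tibble with columns `analyte`, `timepoint`, `replicate`,
#'   `value` (nonnegative raw assay values, e.g. µg per embryo pool).
#' @param baseline Baseline timepoint label; defaults to the first level of
#'   `timepoint`.
#' @param alpha Significance threshold on the raw p-value (default 0.05).
#' @param scale Value the baseline mean is mapped to (1 for fold-of-baseline,
#'   100 for percent).
#' @return A tibble with one row per analyte x timepoint: `n`, `mean`
#'   (normalized), `sem` (normalized standard error of the mean), `p_value`
#'   (Student t vs baseline; `NA` for the baseline row), `significant`.
#' @export
#' @examples
#' sim <- simulate_stores(seed = 1)
#' analyze_stores(sim$assay)
analyze_stores <- function(assay, baseline = NULL, alpha = 0.05, scale = 1) {
  require_columns(assay, c("analyte", "timepoint", "replicate", "value"),
                  "`assay`")
  alpha <- check_fraction(alpha, "alpha")
  if (any(is.na(assay$value))) abort("Store assay values must not be missing.")
  if (any(assay$value < 0)) abort("Store assay values must be nonnegative.")
  tp_levels <- timepoint_levels(assay$timepoint)
  if (is.null(baseline)) baseline <- tp_levels[1L]
  if (!baseline %in% tp_levels) {
    abort(sprintf("Baseline timepoint '%s' not present in `assay`.", baseline))
  }
  assay <- assay %>%
    mutate(timepoint = factor(as.character(.data$timepoint), levels = tp_levels))

  counts <- assay %>% dplyr::count(.data$analyte, .data$timepoint)
  if (any(counts$n < 2L)) {
    abort("Every analyte x timepoint needs at least 2 replicates.")
  }

  base_means <- assay %>%
    filter(as.character(.data$timepoint) == baseline) %>%
    group_by(.data$analyte) %>%
    summarise(base_mean = mean(.data$value), .groups = "drop")
  if (any(base_means$base_mean == 0)) {
    abort("Baseline mean is zero for at least one analyte; cannot normalize.")
  }

  normalized <- assay %>%
    left_join(base_means, by = "analyte") %>%
    mutate(norm_value = .data$value * scale / .data$base_mean)

  base_values <- normalized %>%
    filter(as.character(.data$timepoint) == baseline) %>%
    select("analyte", base_value = "norm_value")
  base_list <- split(base_values$base_value, base_values$analyte)

  normalized %>%
    group_by(.data$analyte, .data$timepoint) %>%
    summarise(
      n = n(),
      mean = mean(.data$norm_value),
      sem = sd(.data$norm_value) / sqrt(n()),
      values = list(.data$norm_value),
      .groups = "drop"
    ) %>%
    mutate(
      p_value = purrr::pmap_dbl(
        list(.data$analyte, as.character(.data$timepoint), .data$values),
        function(an, tp, vals) {
          if (tp == baseline) return(NA_real_)
          bv <- base_list[[an]]
          if (sd(vals) == 0 && sd(bv) == 0) {
            return(if (isTRUE(all.equal(mean(vals), mean(bv)))) 1 else NA_real_)
          }
          t.test(bv, vals, var.equal = TRUE)$p.value
        }
      ),
      significant = !is.na(.data$p_value) & .data$p_value < alpha
    ) %>%
    select(-"values")
}
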