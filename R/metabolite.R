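#' Normalize GC-MS peak areas to the spiked internal standard
#'
#' Each sample of a GC-MS run carries an isotope-labeled internal standard
#' (D4-succinate in the default naming) whose peak area tracks per-sample
#' instrument variation — injection volume, derivatization efficiency,
#' detector drift. Dividing every metabolite peak area by its own sample's
#' standard area removes that variation. Samples whose standard is missing or
#' nonpositive (a failed injection) are dropped entirely, with a warning.
#'
#' @param tc Long-format peak table: columns `sample_id`, `timepoint`,
#'   `replicate`, `metabolite`, `peak_area`. The internal standard appears as
#'   a metabolite row per sample. Missing peak areas are `NA` (below
#'   detection), which is distinct from a measured zero.
#' @param standard Metabolite name of the internal standard
#'   (default `"D4-succinate"`).
#' @return A tibble with the standard rows removed and a new column
#'   `abundance` = `peak_area` / standard area of the same sample. `NA` peak
#'   areas stay `NA`.
#' @export
#' @examples
#' sim <- simulate_metabolome(seed = 1)
#' normalize_to_standard(sim$timecourse)
normalize_to_standard <- function(tc, standard = "D4-succinate") {
  require_columns(tc, c("sample_id", "timepoint", "replicate", "metabolite",
                        "peak_area"), "`tc`")
  tc <- as_tibble(tc)
  std <- tc %>%
    filter(.data$metabolite == standard) %>%
    select("sample_id", standard_area = "peak_area")
  if (nrow(std) == 0L) {
    abort(sprintf("Internal standard '%s' not found in `tc`.", standard))
  }
  if (anyDuplicated(std$sample_id) > 0L) {
    abort("Each sample must carry exactly one internal-standard row.")
  }
  out <- tc %>%
    filter(.data$metabolite != standard) %>%
    left_join(std, by = "sample_id")
  bad <- out %>%
    filter(is.na(.data$standard_area) | .data$standard_area <= 0) %>%
    distinct(.data$sample_id)
  if (nrow(bad) > 0L) {
    warn(sprintf(
      "Dropping %d sample(s) with missing or nonpositive internal standard: %s.",
      nrow(bad), paste(head(bad$sample_id, 5L), collapse = ", ")
    ))
    out <- out %>% filter(!.data$sample_id %in% bad$sample_id)
  }
  out %>%
    mutate(abundance = .data$peak_area / .data$standard_area) %>%
    select(-"standard_area")
}

#' Rescale each metabolite relative to the baseline stage
#'
#' Expresses every normalized abundance relative to a summary statistic
#' (median by default) of the earliest stage, scaled so the baseline
#' statistic maps exactly to `scale` (100 by default): a value of 200 means
#' twice the baseline median. Metabolites whose baseline statistic is zero —
#' undetectable at the onset of the series — cannot be rescaled; their
#' normalized values are passed through unchanged and flagged with
#' `baseline_detectable = FALSE`.
#'
#' @param tc Output of [normalize_to_standard()] (columns `metabolite`,
#'   `timepoint`, `abundance`, ...).
#' @param baseline Timepoint label of the baseline stage (e.g. `"0-2h"`).
#' @param scale Value the baseline statistic is mapped to (default 100).
#' @param statistic Baseline summary: `"median"` (default) or `"mean"`,
#'   computed over non-missing baseline values.
#' @return The input tibble with added columns `rel_abundance` and
#'   `baseline_detectable`.
#' @export
relative_to_baseline <- function(tc, baseline, scale = 100,
                                 statistic = c("median", "mean")) {
  statistic <- arg_match(statistic)
  require_columns(tc, c("metabolite", "timepoint", "abundance"), "`tc`")
  if (!baseline %in% as.character(tc$timepoint)) {
    abort(sprintf("Baseline timepoint '%s' not present in `tc`.", baseline))
  }
  stat_fun <- if (statistic == "median") median else mean
  base <- tc %>%
    filter(as.character(.data$timepoint) == baseline) %>%
    group_by(.data$metabolite) %>%
    summarise(
      n_base = sum(!is.na(.data$abundance)),
      base_stat = if (sum(!is.na(.data$abundance)) > 0)
        stat_fun(.data$abundance[!is.na(.data$abundance)]) else NA_real_,
      .groups = "drop"
    )
  no_base <- base$metabolite[base$n_base == 0L]
  if (length(no_base) > 0L) {
    abort(sprintf(
      "Metabolite(s) with no non-missing baseline value: %s.",
      paste(head(no_base, 5L), collapse = ", ")
    ))
  }
  tc %>%
    left_join(select(base, "metabolite", "base_stat"), by = "metabolite") %>%
    mutate(
      baseline_detectable = .data$base_stat > 0,
      rel_abundance = ifelse(.data$baseline_detectable,
                             .data$abundance * scale / .data$base_stat,
                             .data$abundance)
    ) %>%
    select(-"base_stat")
}

#' Welch two-sample t-test with degenerate-case conventions
#'
#' Unpaired t-test with the Welch correction for unequal variances
#' (Welch–Satterthwaite degrees of freedom), two-sided. Two conventions cover
#' inputs the textbook formulas reject: if both groups have zero variance and
#' equal means the groups are indistinguishable, so t = 0 and p = 1; if both
#' variances are zero but the means differ, the statistic is undefined and
#' the result is flagged `degenerate = TRUE` with `p_value = NA`.
#'
#' @param x,y Numeric vectors, at least 2 non-missing values each.
#' @return One-row tibble: `t`, `df`, `p_value`, `n_x`, `n_y`, `degenerate`.
#' @export
#' @examples
#' welch_test(c(1, 2, 3), c(2, 3, 4))
welch_test <- function(x, y) {
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  if (length(x) < 2L || length(y) < 2L) {
    abort("Both groups need at least 2 non-missing values.")
  }
  if (var(x) == 0 && var(y) == 0) {
    if (isTRUE(all.equal(mean(x), mean(y)))) {
      return(tibble(t = 0, df = length(x) + length(y) - 2, p_value = 1,
                    n_x = length(x), n_y = length(y), degenerate = FALSE))
    }
    return(tibble(t = NA_real_, df = NA_real_, p_value = NA_real_,
                  n_x = length(x), n_y = length(y), degenerate = TRUE))
  }
  ht <- t.test(x, y, var.equal = FALSE)
  tibble(
    t = unname(ht$statistic),
    df = unname(ht$parameter),
    p_value = ht$p.value,
    n_x = length(x), n_y = length(y),
    degenerate = FALSE
  )
}

#' Per-timepoint box-plot summaries and baseline comparisons
#'
#' For every metabolite and timepoint, computes replicate count, the box-plot
#' five-number summary (min, first quartile, median, third quartile, max) on
#' the baseline-relative scale, and a Welch t-test of that timepoint's
#' replicates against the baseline replicates. The baseline row itself gets
#' no p-value (self-comparison is skipped) and is never flagged significant.
#' Because the baseline rescaling multiplies all of a metabolite's values by
#' one constant, the p-values are identical whether computed on normalized or
#' rescaled values.
#'
#' @param tc Output of [relative_to_baseline()].
#' @param baseline Baseline timepoint label.
#' @param alpha Significance threshold (default 0.01; applied to raw
#'   p-values, matching per-timepoint reporting without multiplicity
#'   correction).
#' @param adjust If `TRUE`, add a `p_adjust` column with Benjamini–Hochberg
#'   adjusted p-values across all metabolite-timepoint tests; the
#'   `significant` flag still uses the raw p-value.
#' @return A tibble, one row per metabolite x timepoint: `metabolite`,
#'   `timepoint`, `n`, `min`, `q1`, `median`, `q3`, `max`, `p_value`,
#'   `significant`, `baseline_detectable` (plus `p_adjust` if requested).
#'   Timepoints with fewer than 2 replicates get `NA` p-values.
#' @export
summarize_timecourse <- function(tc, baseline, alpha = 0.01, adjust = FALSE) {
  require_columns(tc, c("metabolite", "timepoint", "rel_abundance",
                        "baseline_detectable"), "`tc`")
  alpha <- check_fraction(alpha, "alpha")
  tp_levels <- timepoint_levels(tc$timepoint)
  if (!baseline %in% tp_levels) {
    abort(sprintf("Baseline timepoint '%s' not present in `tc`.", baseline))
  }
  tc <- tc %>%
    mutate(timepoint = factor(as.character(.data$timepoint), levels = tp_levels)) %>%
    arrange(.data$metabolite, .data$timepoint)

  base_values <- tc %>%
    filter(as.character(.data$timepoint) == baseline, !is.na(.data$rel_abundance)) %>%
    select("metabolite", base_value = "rel_abundance")

  out <- tc %>%
    filter(!is.na(.data$rel_abundance)) %>%
    group_by(.data$metabolite, .data$timepoint) %>%
    summarise(
      n = n(),
      min = min(.data$rel_abundance),
      q1 = quantile(.data$rel_abundance, 0.25, names = FALSE),
      median = median(.data$rel_abundance),
      q3 = quantile(.data$rel_abundance, 0.75, names = FALSE),
      max = max(.data$rel_abundance),
      values = list(.data$rel_abundance),
      baseline_detectable = all(.data$baseline_detectable),
      .groups = "drop"
    )

  base_list <- split(base_values$base_value, base_values$metabolite)
  out <- out %>%
    mutate(
      p_value = purrr::pmap_dbl(
        list(.data$metabolite, as.character(.data$timepoint), .data$values, .data$n),
        function(met, tp, vals, nn) {
          if (tp == baseline) return(NA_real_)
          bv <- base_list[[met]]
          if (nn < 2L || length(bv) < 2L) return(NA_real_)
          welch_test(bv, vals)$p_value
        }
      ),
      significant = !is.na(.data$p_value) & .data$p_value < alpha
    ) %>%
    select(-"values")
  if (isTRUE(adjust)) {
    out <- out %>% mutate(p_adjust = stats::p.adjust(.data$p_value, "BH"))
  }
  out
}

#' Within-sample ratio of two metabolites across the time course
#'
#' Forms the ratio of two metabolites' normalized abundances inside each
#' sample — for example lactate to pyruvate, whose constancy across stages
#' indicates an unchanging redox balance. Samples in which either metabolite
#' is missing, or the denominator is nonpositive, are excluded (with a
#' message of how many were dropped).
#'
#' @param tc Output of [normalize_to_standard()].
#' @param numerator,denominator Metabolite names.
#' @return A tibble `sample_id`, `timepoint`, `replicate`, `ratio`.
#' @export
ratio_series <- function(tc, numerator, denominator) {
  require_columns(tc, c("sample_id", "timepoint", "replicate", "metabolite",
                        "abundance"), "`tc`")
  for (met in c(numerator, denominator)) {
    if (!met %in% tc$metabolite) {
      abort(sprintf("Metabolite '%s' not present in `tc`.", met))
    }
  }
  wide <- tc %>%
    filter(.data$metabolite %in% c(numerator, denominator)) %>%
    select("sample_id", "timepoint", "replicate", "metabolite", "abundance") %>%
    tidyr::pivot_wider(names_from = "metabolite", values_from = "abundance")
  num <- wide[[numerator]]
  den <- wide[[denominator]]
  usable <- !is.na(num) & !is.na(den) & den > 0
  n_drop <- sum(!usable)
  if (all(!usable)) {
    abort("No sample has usable values for both metabolites.")
  }
  if (n_drop > 0L) {
    inform(sprintf(
      "Excluding %d sample(s) with missing values or nonpositive denominator.",
      n_drop
    ))
  }
  wide %>%
    filter(usable) %>%
    mutate(ratio = .data[[numerator]] / .data[[denominator]]) %>%
    select("sample_id", "timepoint", "replicate", "ratio")
}
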