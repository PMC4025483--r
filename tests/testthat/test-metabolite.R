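test_that("internal-standard normalization divides by the sample's standard", {
  vals <- matrix(c(50, 10, 30, 20), nrow = 2,
                 dimnames = list(c("lactate", "pyruvate"), c("t01", "t02")))
  # standard 1 everywhere: identity
  tc <- peak_table(vals, std = 1)
  norm <- normalize_to_standard(tc)
  expect_equal(norm$abundance, norm$peak_area)

  # standard 2: halved
  tc2 <- peak_table(vals, std = 2)
  norm2 <- normalize_to_standard(tc2)
  expect_equal(norm2$abundance[norm2$metabolite == "lactate" &
                                 norm2$timepoint == "t01"], 25)

  # a zero standard drops the whole sample and downstream n shrinks
  tc3 <- peak_table(vals, reps = 3, std = 1)
  tc3$peak_area[tc3$sample_id == "S_t01_r2" &
                  tc3$metabolite == "D4-succinate"] <- 0
  expect_warning(norm3 <- normalize_to_standard(tc3), "nonpositive internal standard")
  expect_false("S_t01_r2" %in% norm3$sample_id)
  n_t01 <- sum(norm3$metabolite == "lactate" & norm3$timepoint == "t01")
  expect_equal(n_t01, 2L)

  # NA peak areas stay NA (below detection, not zero)
  tc4 <- peak_table(vals, std = 2)
  tc4$peak_area[1] <- NA
  norm4 <- normalize_to_standard(tc4)
  expect_true(is.na(norm4$abundance[1]))
})

test_that("baseline rescaling maps the baseline statistic exactly to the scale", {
  vals <- matrix(c(2, 4, 6, 8, 8, 8), nrow = 1,
                 dimnames = list("x", sprintf("t%02d", 1:6)))
  # three baseline replicates 2, 4, 6 (median 4); later value 8 -> 200
  tc <- tibble::tibble(
    sample_id = sprintf("s%d", 1:4),
    timepoint = factor(c("t01", "t01", "t01", "t02"), levels = c("t01", "t02")),
    replicate = c(1, 2, 3, 1),
    metabolite = "x",
    abundance = c(2, 4, 6, 8)
  )
  out <- relative_to_baseline(tc, "t01")
  expect_equal(out$rel_abundance, c(50, 100, 150, 200))
  expect_equal(median(out$rel_abundance[out$timepoint == "t01"]), 100)

  # fixed point holds for every metabolite of a generated panel
  sim <- simulate_metabolome(seed = 2)
  norm <- normalize_to_standard(sim$timecourse)
  resc <- relative_to_baseline(norm, "0-2h")
  base_medians <- resc %>%
    dplyr::filter(timepoint == "0-2h") %>%
    dplyr::group_by(metabolite) %>%
    dplyr::summarise(med = median(rel_abundance))
  expect_equal(base_medians$med, rep(100, nrow(base_medians)))

  # zero baseline: flagged, values passed through unscaled
  tc0 <- tc %>% dplyr::mutate(abundance = c(0, 0, 0, 8))
  out0 <- relative_to_baseline(tc0, "t01")
  expect_false(any(out0$baseline_detectable))
  expect_equal(out0$rel_abundance, c(0, 0, 0, 8))

  expect_error(relative_to_baseline(tc, "t99"), "not present")
})

test_that("the Welch test matches the hand-formula oracle", {
  # frozen oracle values computed from the Welch formulas
  res <- welch_test(c(1, 2, 3), c(2, 3, 4))
  expect_equal(res$t, -1.224744871392, tolerance = 1e-10)
  expect_equal(res$df, 4, tolerance = 1e-10)
  expect_equal(res$p_value, 0.287864134727, tolerance = 1e-10)

  # random small-sample pairs against the formula oracle
  set.seed(21)
  for (rep in 1:100) {
    x <- rnorm(sample(2:9, 1), sd = runif(1, 0.5, 3))
    y <- rnorm(sample(2:9, 1), mean = runif(1, -1, 1), sd = runif(1, 0.5, 3))
    got <- welch_test(x, y)
    want <- welch_oracle(x, y)
    expect_equal(got$t, want$t, tolerance = 1e-10)
    expect_equal(got$df, want$df, tolerance = 1e-10)
    expect_equal(got$p_value, want$p, tolerance = 1e-10)
  }
})

test_that("Welch degenerate conventions: identical groups, zero-variance groups", {
  res <- welch_test(c(5, 5, 5), c(5, 5, 5))
  expect_equal(res$t, 0)
  expect_equal(res$p_value, 1)
  expect_false(res$degenerate)

  res2 <- welch_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(res2$t, 0)
  expect_equal(res2$p_value, 1)

  res3 <- welch_test(c(5, 5, 5), c(7, 7, 7))
  expect_true(res3$degenerate)
  expect_true(is.na(res3$p_value))

  expect_error(welch_test(1, c(1, 2)), "at least 2")
})

test_that("summaries flag planted changes and spare the baseline row", {
  sim <- simulate_metabolome(seed = 3)
  norm <- normalize_to_standard(sim$timecourse)
  resc <- relative_to_baseline(norm, "0-2h")
  s <- summarize_timecourse(resc, "0-2h", alpha = 0.01)

  expect_true(all(c("n", "min", "q1", "median", "q3", "max") %in% names(s)))
  expect_true(all(s$min <= s$q1 & s$q1 <= s$median &
                    s$median <= s$q3 & s$q3 <= s$max))

  base_rows <- s %>% dplyr::filter(timepoint == "0-2h")
  expect_true(all(is.na(base_rows$p_value)))
  expect_false(any(base_rows$significant))

  # planted ten-fold rise: final bins flagged, final median near 1000
  g3p <- s %>% dplyr::filter(metabolite == "g3p_like")
  final <- g3p[g3p$timepoint == "22-24h", ]
  expect_true(final$significant)
  expect_gt(final$median, 800)
  expect_lt(final$median, 1200)

  # planted 98% drop: final-bin median near 2 on the 0-100 scale
  kyn <- s %>% dplyr::filter(metabolite == "kynurenine_like",
                             timepoint == "22-24h")
  expect_true(kyn$significant)
  expect_gt(kyn$median, 2 * exp(-0.35))
  expect_lt(kyn$median, 2 * exp(0.35))
})

test_that("summaries are invariant to input row order", {
  sim <- simulate_metabolome(seed = 4)
  norm <- normalize_to_standard(sim$timecourse)
  resc <- relative_to_baseline(norm, "0-2h")
  s1 <- summarize_timecourse(resc, "0-2h")
  set.seed(1)
  s2 <- summarize_timecourse(resc[sample(nrow(resc)), ], "0-2h")
  expect_equal(s1, s2)
})

test_that("a timepoint with a single replicate gets no p-value", {
  tc <- tibble::tibble(
    sample_id = sprintf("s%d", 1:5),
    timepoint = factor(c("t01", "t01", "t01", "t02", "t02"),
                       levels = c("t01", "t02")),
    replicate = c(1, 2, 3, 1, 2),
    metabolite = "x",
    abundance = c(2, 4, 6, 8, NA)
  )
  resc <- relative_to_baseline(tc, "t01")
  s <- summarize_timecourse(resc, "t01")
  t02 <- s[s$timepoint == "t02", ]
  expect_equal(t02$n, 1L)
  expect_true(is.na(t02$p_value))
  expect_false(t02$significant)
})

test_that("metabolite ratios are within-sample and exclude unusable samples", {
  sim <- simulate_metabolome(seed = 5)
  norm <- normalize_to_standard(sim$timecourse)

  # numerator = denominator: all ratios exactly 1
  rs <- ratio_series(norm, "lactate_like", "lactate_like")
  expect_true(all(rs$ratio == 1))

  # planted proportional pair: both flat trajectories scaled by the same
  # per-sample drift, so the ratio is lognormal around 1 at every stage
  rs2 <- ratio_series(norm, "lactate_like", "pyruvate_like")
  by_tp <- rs2 %>% dplyr::group_by(timepoint) %>%
    dplyr::summarise(med = median(ratio))
  expect_true(all(abs(log(by_tp$med)) < 3 * 0.15 * sqrt(2)))

  # zero denominator: sample excluded with a message
  norm2 <- norm
  idx <- which(norm2$metabolite == "pyruvate_like")[1]
  norm2$abundance[idx] <- 0
  expect_message(rs3 <- ratio_series(norm2, "lactate_like", "pyruvate_like"),
                 "Excluding 1 sample")
  expect_equal(nrow(rs3), nrow(rs2) - 1L)

  expect_error(ratio_series(norm, "lactate_like", "nope"), "not present")
})
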