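# Synthetic-data generators with recorded ground truth. These emulate the
# structure of a staged embryonic series — a low-rank expression matrix with
# planted temporal patterns, an annotation catalog with planted enrichment,
# and metabolite / nutrient-store trajectories with planted fold changes —
# so every analysis stage can be scored against known truth.

#' Stage labels for a 2-hour-binned embryonic series
#'
#' @param n_timepoints Number of stages. For 12 stages the canonical 0–24 h
#'   AEL 2-hour bins (`"0-2h"` … `"22-24h"`) are produced; otherwise generic
#'   ordered labels `"t01"`, `"t02"`, ….
#' @return Character vector of ordered stage labels.
#' @export
stage_labels <- function(n_timepoints) {
  n_timepoints <- check_count(n_timepoints, "n_timepoints", min = 1L)
  if (n_timepoints == 12L) {
    sprintf("%d-%dh", 2 * (0:11), 2 * (0:11) + 2)
  } else {
    sprintf("t%02d", seq_len(n_timepoints))
  }
}

# Raw (pre-orthogonalization) temporal shape vectors. The non-constant
# shapes are smooth and slightly asymmetric: gene induction is graded over
# adjacent stages, and the asymmetry gives the orthogonalized vector a
# unique largest-magnitude element (positive, at the late end), so the
# decomposition's sign-orientation convention reproduces the planted
# orientation stably under noise. A hard symmetric step would instead tie
# its extreme elements and leave the recovered sign at the mercy of noise.
pattern_shape <- function(shape, n_timepoints) {
  t <- seq_len(n_timepoints)
  switch(shape,
    constant = rep(1, n_timepoints),
    # broad upregulation midway: sigmoid induction centered just past
    # mid-series
    step_up_mid = stats::plogis(t - 0.55 * (n_timepoints + 1)),
    # decreases at mid-series, rises late above the early level
    u_shape = (t - 0.45 * (n_timepoints + 1))^2,
    abort(sprintf("Unknown pattern shape '%s'.", shape))
  )
}

# Gram-Schmidt orthonormalization of pattern rows, in the listed order.
orthonormalize_rows <- function(mat) {
  out <- mat
  for (i in seq_len(nrow(mat))) {
    v <- mat[i, ]
    if (i > 1L) {
      for (j in seq_len(i - 1L)) v <- v - sum(v * out[j, ]) * out[j, ]
    }
    nrm <- sqrt(sum(v^2))
    if (nrm < 1e-10) {
      abort(sprintf(
        "Pattern %d is linearly dependent on earlier patterns; shapes must be orthogonalizable.",
        i
      ))
    }
    out[i, ] <- v / nrm
  }
  out
}

#' Default planted expression patterns
#'
#' Three patterns emulating the dominant programs of an embryonic series:
#' a constant baseline program carried by every gene, a mid-series step-up
#' (the coordinate induction of metabolic genes midway through development),
#' and a U-shape that dips at mid-series and rises late. Weights are the
#' planted singular values; `member_frac` is the fraction of genes loading
#' on each pattern.
#'
#' @return A list of pattern specifications, each a list with `shape`,
#'   `weight`, `member_frac`.
#' @export
default_expression_patterns <- function() {
  list(
    list(shape = "constant", weight = 60, member_frac = 1.0),
    list(shape = "step_up_mid", weight = 25, member_frac = 0.3),
    list(shape = "u_shape", weight = 12, member_frac = 0.2)
  )
}

#' Simulate an expression time course with planted temporal patterns
#'
#' Builds `baseline_offset + sum_p weight_p * u_p v_p' + noise`, clipped at
#' zero, where the `v_p` are the requested temporal shapes orthonormalized in
#' order (so each planted pattern is identifiable by SVD) and the `u_p` are
#' unit-norm nonnegative loading vectors supported on a random
#' `member_frac` subset of genes. Because loadings and patterns are unit
#' norm, each `weight` is the planted singular value of its component; the
#' recorded signal-to-noise ratio is `weight / (noise_sd * (sqrt(n_genes) +
#' sqrt(n_timepoints)))`, the weight relative to the expected spectral edge
#' of the Gaussian noise matrix.
#'
#' @param n_genes Number of genes (default 17000, the scale of a
#'   genome-wide series).
#' @param n_timepoints Number of ordered stages (default 12).
#' @param patterns List of pattern specs (`shape` one of `"constant"`,
#'   `"step_up_mid"`, `"u_shape"`, or a custom numeric vector of length
#'   `n_timepoints`; `weight` > 0; `member_frac` in (0, 1]). Defaults to
#'   [default_expression_patterns()].
#' @param noise_sd Standard deviation of additive Gaussian noise (default
#'   0.008, which puts the weakest default pattern at SNR ~ 11 at the
#'   default dimensions).
#' @param baseline_offset Constant abundance floor added to every entry
#'   (default 1). The offset matrix has the constant temporal direction, so
#'   it merges into the constant pattern's component without disturbing the
#'   other planted patterns; a positive floor keeps the noiseless signal
#'   nonnegative, so the zero clip only touches rare extreme noise draws
#'   instead of systematically distorting the planted factors.
#' @param seed RNG seed; output is byte-identical for a fixed seed.
#' @return A list: `expression` (tibble, gene_id + one column per stage) and
#'   `truth` (planted orthonormal `patterns` matrix, unit-norm `loadings`
#'   matrix, `weights`, per-pattern `members` gene-ID lists, `snr`, and the
#'   generator parameters).
#' @export
#' @examples
#' sim <- simulate_expression(n_genes = 500, n_timepoints = 12, seed = 1)
#' dim(sim$expression)
#' sim$truth$snr
simulate_expression <- function(n_genes = 17000, n_timepoints = 12,
                                patterns = default_expression_patterns(),
                                noise_sd = 0.008, baseline_offset = 1,
                                seed = 1) {
  n_genes <- check_count(n_genes, "n_genes", min = 2L)
  n_timepoints <- check_count(n_timepoints, "n_timepoints", min = 2L)
  if (n_genes < n_timepoints) {
    abort("`n_genes` must be at least `n_timepoints`.")
  }
  if (!is.numeric(noise_sd) || noise_sd < 0) abort("`noise_sd` must be >= 0.")
  if (!is.numeric(baseline_offset) || baseline_offset < 0) {
    abort("`baseline_offset` must be >= 0.")
  }
  if (length(patterns) == 0L && noise_sd == 0) {
    abort("Degenerate spec: no patterns and no noise.")
  }
  n_p <- length(patterns)
  shapes <- matrix(0, nrow = max(n_p, 1L), ncol = n_timepoints)
  weights <- numeric(n_p)
  fracs <- numeric(n_p)
  for (i in seq_len(n_p)) {
    p <- patterns[[i]]
    if (is.numeric(p$shape)) {
      if (length(p$shape) != n_timepoints) {
        abort("Custom pattern vectors must have length `n_timepoints`.")
      }
      shapes[i, ] <- p$shape
    } else {
      shapes[i, ] <- pattern_shape(p$shape, n_timepoints)
    }
    if (!is.numeric(p$weight) || p$weight <= 0) abort("Pattern weights must be > 0.")
    if (!is.numeric(p$member_frac) || p$member_frac <= 0 || p$member_frac > 1) {
      abort("`member_frac` must be in (0, 1].")
    }
    weights[i] <- p$weight
    fracs[i] <- p$member_frac
  }

  gene_ids <- sprintf("G%06d", seq_len(n_genes))
  stages <- stage_labels(n_timepoints)

  with_seed(seed, {
    v <- if (n_p > 0L) orthonormalize_rows(shapes) else
      matrix(0, 0L, n_timepoints)
    u <- matrix(0, n_genes, n_p)
    members <- vector("list", n_p)
    for (i in seq_len(n_p)) {
      sz <- max(1L, round(fracs[i] * n_genes))
      idx <- sort(sample.int(n_genes, sz))
      members[[i]] <- gene_ids[idx]
      load <- abs(rnorm(sz))
      u[idx, i] <- load / sqrt(sum(load^2))
    }
    # orthonormalize the loading vectors as well: nonnegative loadings on
    # overlapping member sets are strongly correlated, and only with
    # orthonormal factors on both sides are the planted components exactly
    # the SVD of the noiseless signal (the planted idealization)
    if (n_p > 0L) u <- t(orthonormalize_rows(t(u)))
    x <- matrix(baseline_offset, n_genes, n_timepoints)
    if (n_p > 0L) x <- x + u %*% (weights * v)
    if (noise_sd > 0) {
      x <- x + matrix(rnorm(n_genes * n_timepoints, sd = noise_sd),
                      n_genes, n_timepoints)
    }
    x <- pmax(x, 0)

    expression <- as_tibble(setNames(
      c(list(gene_ids),
        lapply(seq_len(n_timepoints), function(j) x[, j])),
      c("gene_id", stages)
    ))
    truth <- list(
      patterns = v,
      loadings = u,
      weights = weights,
      members = members,
      gene_ids = gene_ids,
      stage_labels = stages,
      noise_sd = noise_sd,
      baseline_offset = baseline_offset,
      snr = if (noise_sd > 0) {
        weights / (noise_sd * (sqrt(n_genes) + sqrt(n_timepoints)))
      } else {
        rep(Inf, n_p)
      },
      seed = seed
    )
    list(expression = expression, truth = truth)
  })
}

#' Simulate an annotation catalog with planted enrichment
#'
#' Draws `K` annotated genes from the universe such that genes in the top-`m`
#' planted-loading list of one pattern are over-represented by a chosen
#' ratio: the number of annotated genes falling inside the top-`m` set is
#' drawn as Binomial(K, min(1, ratio * m / M)), versus the null expectation
#' K * m / M at ratio 1. The realized ratio is recorded in the returned
#' truth so recovery can be scored without re-running the generator.
#'
#' @param truth The `truth` component of [simulate_expression()].
#' @param K Catalog size (default 1228, the scale of a metabolic-gene
#'   catalog).
#' @param ratio Planted enrichment ratio, >= 1 (1 = no enrichment).
#' @param pattern Which planted pattern's loading order defines the top set
#'   (default 2).
#' @param top_m Size of the top-loading set the enrichment targets
#'   (default 500).
#' @param seed RNG seed.
#' @return A list: `catalog` (an [annotation_catalog()]) and `truth` (a list
#'   with `ratio_requested`, `ratio_realized`, `k_top`, `top_m`, `pattern`,
#'   `top_genes`).
#' @export
simulate_annotations <- function(truth, K = 1228, ratio = 1, pattern = 2,
                                 top_m = 500, seed = 1) {
  gene_ids <- truth$gene_ids
  M <- length(gene_ids)
  K <- check_count(K, "K", min = 1L)
  if (K > M) abort(sprintf("K (%d) must be <= universe size (%d).", K, M))
  if (!is.numeric(ratio) || ratio < 1) abort("`ratio` must be >= 1.")
  pattern <- check_count(pattern, "pattern", min = 1L)
  if (pattern > ncol(truth$loadings)) {
    abort("`pattern` exceeds the number of planted patterns.")
  }
  top_m <- check_count(top_m, "top_m", min = 1L)
  if (top_m > M) abort("`top_m` must be <= universe size.")

  p_top <- min(1, ratio * top_m / M)
  if (K * p_top > top_m) {
    abort(sprintf(
      "Infeasible ratio: expected overlap (%.1f) exceeds top_m (%d).",
      K * p_top, top_m
    ))
  }
  load <- truth$loadings[, pattern]
  ord <- order(-load, gene_ids, method = "radix")
  top_genes <- gene_ids[ord[seq_len(top_m)]]
  rest_genes <- gene_ids[ord[-seq_len(top_m)]]

  with_seed(seed, {
    k_top <- stats::rbinom(1L, K, p_top)
    k_top <- min(k_top, top_m, K)
    k_top <- max(k_top, K - length(rest_genes))
    annotated <- c(
      sample(top_genes, k_top),
      sample(rest_genes, K - k_top)
    )
    list(
      catalog = annotation_catalog(gene_ids, sort(annotated),
                                   label = "planted catalog"),
      truth = list(
        ratio_requested = ratio,
        ratio_realized = k_top * M / (K * top_m),
        k_top = k_top,
        top_m = top_m,
        pattern = pattern,
        top_genes = top_genes
      )
    )
  })
}

#' Default metabolite trajectory panel
#'
#' Named presets emulating the magnitude classes seen across an embryonic
#' GC-MS survey: a ~10-fold rise (glycerol-3-phosphate-like), a ~100-fold
#' rise (uric-acid-like), a late 98% drop (kynurenine-like; fold 50), an
#' early 10-fold drop followed by recovery (beta-alanine-like), a ~5-fold
#' rise (citrate-like), a ~10-fold decline (aspartate-like), and stable
#' controls.
#'
#' @return A list of trajectory specs, each a list with `name`, `shape`
#'   (one of `"flat"`, `"fold_rise"`, `"fold_drop"`, `"u_shape"`,
#'   `"early_drop_late_rise"`), and `fold`.
#' @export
default_metabolome_trajectories <- function() {
  list(
    list(name = "g3p_like", shape = "fold_rise", fold = 10),
    list(name = "uric_acid_like", shape = "fold_rise", fold = 100),
    list(name = "citrate_like", shape = "fold_rise", fold = 5),
    list(name = "kynurenine_like", shape = "fold_drop", fold = 50),
    list(name = "aspartate_like", shape = "fold_drop", fold = 10),
    list(name = "beta_alanine_like", shape = "early_drop_late_rise", fold = 10),
    list(name = "glutamate_like", shape = "u_shape", fold = 2),
    list(name = "pyruvate_like", shape = "flat", fold = 1),
    list(name = "lactate_like", shape = "flat", fold = 1),
    list(name = "malate_like", shape = "flat", fold = 1)
  )
}

# True (noise-free) trajectory over the series, baseline value 1. Fold
# changes are laid out on the log scale, mirroring the multiplicative nature
# of metabolite pools:
#   fold_rise  — flat for the first quarter, then log-linear rise to `fold`;
#   fold_drop  — flat for the first ~60% of the series (the drop starts after
#                mid-series), then log-linear fall to 1/fold;
#   u_shape    — log-scale dip to 1/fold at mid-series, back to 1;
#   early_drop_late_rise — drop to 1/fold within the first sixth, then
#                log-linear recovery to 1.
trajectory_values <- function(shape, fold, n_timepoints) {
  t <- seq_len(n_timepoints)
  if (!is.numeric(fold) || fold <= 0) abort("Trajectory `fold` must be > 0.")
  ramp <- function(from_idx, start, end) {
    # log-linear from `start` at from_idx to `end` at the final timepoint
    out <- rep(start, n_timepoints)
    span <- n_timepoints - from_idx
    if (span <= 0) {
      out[n_timepoints] <- end
      return(out)
    }
    idx <- from_idx:n_timepoints
    out[idx] <- exp(log(start) + (log(end) - log(start)) *
                      (idx - from_idx) / span)
    out
  }
  switch(shape,
    flat = rep(1, n_timepoints),
    fold_rise = ramp(max(1L, ceiling(n_timepoints / 4)), 1, fold),
    fold_drop = ramp(max(1L, ceiling(0.6 * n_timepoints)), 1, 1 / fold),
    u_shape = {
      mid <- (n_timepoints + 1) / 2
      bump <- 1 - abs(t - mid) / (mid - 1)
      exp(-log(fold) * bump)
    },
    early_drop_late_rise = {
      drop_at <- max(2L, ceiling(n_timepoints / 6))
      v <- ramp(drop_at, 1 / fold, 1)
      v[seq_len(drop_at - 1L)] <- c(1, rep(1 / fold, drop_at - 2L))
      v
    },
    abort(sprintf("Unknown trajectory shape '%s'.", shape))
  )
}

#' Simulate a GC-MS metabolite time course with planted fold changes
#'
#' Each sample's peak areas are `base_area * trajectory(t) * lognormal
#' replicate noise * sample factor`, where the sample factor (lognormal
#' instrument drift) also multiplies the internal-standard row of the same
#' sample — so internal-standard normalization cancels it exactly.
#'
#' @param trajectories List of trajectory specs (see
#'   [default_metabolome_trajectories()]).
#' @param n_replicates Replicates per timepoint (default 7 sample sets).
#' @param n_timepoints Number of stages (default 12 two-hour bins).
#' @param noise_sd SD of lognormal replicate noise on the log scale
#'   (default 0.15, ~15% CV — typical GC-MS replicate error).
#' @param standard_drift_sd SD of the lognormal per-sample instrument factor
#'   (default 0.3).
#' @param base_area Baseline peak area in arbitrary instrument units
#'   (default 1e4).
#' @param standard_name,standard_area Name and nominal area of the internal
#'   standard.
#' @param seed RNG seed.
#' @return A list: `timecourse` (long tibble `sample_id`, `timepoint`,
#'   `replicate`, `metabolite`, `peak_area`, with the internal standard as a
#'   metabolite row per sample, `timepoint` an ordered factor) and `truth`
#'   (matrix of true trajectories, per-sample drift factors, parameters).
#' @export
#' @examples
#' sim <- simulate_metabolome(seed = 1)
#' head(sim$timecourse)
simulate_metabolome <- function(trajectories = default_metabolome_trajectories(),
                                n_replicates = 7, n_timepoints = 12,
                                noise_sd = 0.15, standard_drift_sd = 0.3,
                                base_area = 1e4,
                                standard_name = "D4-succinate",
                                standard_area = 1e4, seed = 1) {
  n_replicates <- check_count(n_replicates, "n_replicates", min = 2L)
  n_timepoints <- check_count(n_timepoints, "n_timepoints", min = 2L)
  if (!is.numeric(noise_sd) || noise_sd < 0) abort("`noise_sd` must be >= 0.")
  if (!is.numeric(standard_drift_sd) || standard_drift_sd < 0) {
    abort("`standard_drift_sd` must be >= 0.")
  }
  if (length(trajectories) == 0L) abort("At least one trajectory is required.")
  names_ <- vapply(trajectories, function(x) x$name, character(1))
  if (anyDuplicated(names_) > 0L) abort("Trajectory names must be unique.")
  if (standard_name %in% names_) {
    abort("A trajectory must not share the internal standard's name.")
  }
  stages <- stage_labels(n_timepoints)
  traj <- vapply(
    trajectories,
    function(x) trajectory_values(x$shape, x$fold, n_timepoints),
    numeric(n_timepoints)
  ) # n_timepoints x n_metabolites
  colnames(traj) <- names_
  rownames(traj) <- stages

  n_samples <- n_timepoints * n_replicates
  grid <- tidyr::expand_grid(
    timepoint = factor(stages, levels = stages),
    replicate = seq_len(n_replicates)
  ) %>%
    mutate(sample_id = sprintf("S_%s_r%d", .data$timepoint, .data$replicate))

  with_seed(seed, {
    drift <- exp(rnorm(n_samples, sd = standard_drift_sd))
    rows <- purrr::map2(grid$timepoint, seq_len(n_samples), function(tp, si) {
      noise <- exp(rnorm(length(names_), sd = noise_sd))
      tibble(
        sample_id = grid$sample_id[si],
        timepoint = tp,
        replicate = grid$replicate[si],
        metabolite = c(names_, standard_name),
        peak_area = unname(c(
          base_area * traj[as.character(tp), ] * noise * drift[si],
          standard_area * drift[si]
        ))
      )
    })
    timecourse <- bind_rows(rows) %>%
      mutate(timepoint = factor(as.character(.data$timepoint), levels = stages))
    truth <- list(
      trajectories = traj,
      drift = setNames(drift, grid$sample_id),
      noise_sd = noise_sd,
      standard_drift_sd = standard_drift_sd,
      base_area = base_area,
      standard_name = standard_name,
      seed = seed
    )
    list(timecourse = timecourse, truth = truth)
  })
}

#' Simulate a nutrient-store assay with a planted trend
#'
#' Emulates replicate bulk assays (e.g. triglyceride on pools of 300 staged
#' embryos): a linear trend from the baseline value to `final_frac` of
#' baseline across the series, with Gaussian replicate noise proportional to
#' the baseline value.
#'
#' @param analyte Analyte label (default `"TAG"`).
#' @param final_frac Final timepoint's true mean as a fraction of baseline
#'   (default 0.3, a depletion to 30%).
#' @param n_replicates Replicates per timepoint (default 6 pools).
#' @param n_timepoints Number of timepoints (default 6, i.e. 4-hour
#'   intervals over a 24-hour series).
#' @param cv Replicate coefficient of variation relative to baseline
#'   (default 0.15).
#' @param baseline_value True baseline mean in assay units (default 100).
#' @param seed RNG seed.
#' @return A list: `assay` (tibble `analyte`, `timepoint`, `replicate`,
#'   `value`, values clipped at 0) and `truth` (true per-timepoint means).
#' @export
simulate_stores <- function(analyte = "TAG", final_frac = 0.3,
                            n_replicates = 6, n_timepoints = 6, cv = 0.15,
                            baseline_value = 100, seed = 1) {
  n_replicates <- check_count(n_replicates, "n_replicates", min = 2L)
  n_timepoints <- check_count(n_timepoints, "n_timepoints", min = 2L)
  if (!is.numeric(final_frac) || final_frac < 0) abort("`final_frac` must be >= 0.")
  if (!is.numeric(cv) || cv < 0) abort("`cv` must be >= 0.")
  tps <- if (n_timepoints == 6L) {
    sprintf("%d-%dh", 4 * (0:5), 4 * (0:5) + 4)
  } else {
    sprintf("t%02d", seq_len(n_timepoints))
  }
  true_means <- baseline_value *
    seq(1, final_frac, length.out = n_timepoints)
  with_seed(seed, {
    assay <- tidyr::expand_grid(
      analyte = analyte,
      timepoint = factor(tps, levels = tps),
      replicate = seq_len(n_replicates)
    ) %>%
      mutate(
        value = pmax(0, true_means[as.integer(.data$timepoint)] +
                       rnorm(dplyr::n(), sd = cv * baseline_value))
      )
    list(
      assay = assay,
      truth = list(
        true_means = setNames(true_means, tps),
        final_frac = final_frac, cv = cv, seed = seed
      )
    )
  })
}
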