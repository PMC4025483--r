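#' Decompose an expression time course into eigengenes
#'
#' Computes the thin singular value decomposition D = U S V' of a
#' genes-by-timepoints matrix, transforming the data from (gene) x (time)
#' space into (eigengene) x (eigentime) space. Each row of V' is an
#' *eigengene*: a unit-norm temporal pattern shared across genes; the matching
#' column of U carries each gene's loading on that pattern. All `r = `number
#' of timepoints patterns are returned (zero singular values retained), so a
#' 12-stage series always yields 12 eigengenes.
#'
#' Because SVD determines each singular pair only up to a joint sign flip, the
#' decomposition is oriented deterministically: each eigengene is flipped so
#' that its largest-magnitude element is positive, with the matching U column
#' flipped in step. The applied flips are recorded in `orientation_signs`.
#'
#' By default the matrix is decomposed as-is: no centering and no log
#' transform. On abundance-scale data this leaves the grand "expressed at a
#' constant level" program in the data, so the leading eigengene typically
#' captures it — centering would remove that pattern entirely. Both a
#' `log1p` transform and column centering are available as options.
#'
#' @param data Expression table accepted by [as_expression_matrix()]; must
#'   have at least as many genes as timepoints.
#' @param transform `"none"` (default) or `"log1p"` applied elementwise before
#'   decomposition.
#' @param center If `TRUE`, subtract each timepoint column's mean before
#'   decomposition. Default `FALSE`.
#'
#' @return An object of class `eigengene_fit` with components:
#'   \describe{
#'     \item{loadings}{genes x r matrix U (orthonormal columns), rownames gene IDs.}
#'     \item{singular_values}{length-r nonincreasing nonnegative vector.}
#'     \item{eigengenes}{r x timepoints matrix V' (orthonormal rows), colnames stage labels.}
#'     \item{fractions}{eigenexpression fractions, summing to 1.}
#'     \item{entropy}{normalized Shannon entropy of the fractions, in \[0, 1\].}
#'     \item{orientation_signs}{the +/-1 flips applied to each pattern.}
#'   }
#' @seealso [eigenexpression_fractions()], [shannon_entropy()],
#'   [rank_genes()], [tidy.eigengene_fit()], [autoplot.eigengene_fit()]
#' @export
#' @examples
#' sim <- simulate_expression(n_genes = 300, n_timepoints = 6, seed = 1)
#' fit <- eigen_decompose(sim$expression)
#' fit$entropy
#' glance(fit)
eigen_decompose <- function(data, transform = c("none", "log1p"),
                            center = FALSE) {
  transform <- arg_match(transform)
  data <- as_expression_matrix(data, require_tall = TRUE)
  x <- expression_values(data)
  if (transform == "log1p") x <- log1p(x)
  if (isTRUE(center)) x <- scale(x, center = TRUE, scale = FALSE)
  r <- ncol(x)
  sv <- svd(x, nu = r, nv = r)

  # deterministic sign orientation: largest-|.| element of each eigengene > 0
  signs <- vapply(seq_len(r), function(j) {
    v <- sv$v[, j]
    i <- which.max(abs(v))
    s <- sign(v[i])
    if (s == 0) 1 else s
  }, numeric(1))
  u <- sweep(sv$u, 2L, signs, `*`)
  v <- sweep(sv$v, 2L, signs, `*`)

  pattern_names <- paste0("pattern", seq_len(r))
  dimnames(u) <- list(data$gene_id, pattern_names)
  eigengenes <- t(v)
  dimnames(eigengenes) <- list(pattern_names, colnames(data)[-1L])

  fractions <- eigenexpression_fractions(sv$d)
  structure(
    list(
      loadings = u,
      singular_values = sv$d,
      eigengenes = eigengenes,
      fractions = fractions,
      entropy = shannon_entropy(fractions),
      orientation_signs = signs,
      gene_ids = data$gene_id,
      stage_labels = colnames(data)[-1L],
      transform = transform,
      center = isTRUE(center)
    ),
    class = "eigengene_fit"
  )
}

#' Eigenexpression fractions of a singular-value spectrum
#'
#' The share of overall expression captured by each eigengene: each singular
#' value divided by the sum of all singular values. Singular values enter
#' linearly (not squared), so the fractions partition the nuclear norm of the
#' matrix.
#'
#' @param singular_values Nonincreasing, nonnegative numeric vector, not all
#'   zero.
#' @return Numeric vector of the same length, summing to 1.
#' @export
#' @examples
#' eigenexpression_fractions(c(3, 2, 1)) # 1/2, 1/3, 1/6
eigenexpression_fractions <- function(singular_values) {
  s <- singular_values
  if (!is.numeric(s) || length(s) == 0L || any(!is.finite(s))) {
    abort("`singular_values` must be a finite numeric vector.")
  }
  if (any(s < 0)) abort("Singular values must be nonnegative.")
  if (is.unsorted(rev(s))) abort("Singular values must be nonincreasing.")
  total <- sum(s)
  if (total == 0) abort("Singular values must not all be zero.")
  s / total
}

#' Normalized Shannon entropy of eigenexpression fractions
#'
#' d = -(1 / ln n) * sum(e_i ln e_i), with 0 * ln 0 taken as 0. The value is
#' 0 when a single pattern carries all expression (fully ordered data) and 1
#' when all n patterns carry equal shares (fully unordered data).
#'
#' @param fractions Nonnegative numeric vector of length >= 2 summing to 1.
#' @param tol Tolerance for the sum-to-one check.
#' @return A number in \[0, 1\].
#' @export
#' @examples
#' shannon_entropy(c(1, 0, 0))   # 0
#' shannon_entropy(rep(1 / 12, 12)) # 1
shannon_entropy <- function(fractions, tol = 1e-8) {
  e <- fractions
  if (!is.numeric(e) || length(e) < 2L || any(!is.finite(e))) {
    abort("`fractions` must be a finite numeric vector of length >= 2.")
  }
  if (any(e < 0)) abort("Fractions must be nonnegative.")
  if (abs(sum(e) - 1) > tol) {
    abort(sprintf("Fractions must sum to 1 (got %.10f).", sum(e)))
  }
  nz <- e[e > 0]
  d <- -sum(nz * log(nz)) / log(length(e))
  # guard against roundoff poking outside [0, 1]
  min(max(d, 0), 1)
}

#' Cumulative share of the top-k eigengenes
#'
#' Sum of the `top_k` largest eigenexpression fractions — e.g. the share of
#' total expression explained by the three dominant patterns.
#'
#' @param fractions Eigenexpression fractions.
#' @param top_k Number of leading fractions to sum, between 1 and
#'   `length(fractions)`.
#' @return A number in (0, 1\].
#' @export
#' @examples
#' cumulative_fraction(c(0.5, 0.3, 0.2), 2) # 0.8
cumulative_fraction <- function(fractions, top_k) {
  if (!is.numeric(fractions) || length(fractions) == 0L) {
    abort("`fractions` must be a numeric vector.")
  }
  top_k <- check_count(top_k, "top_k", min = 1L)
  if (top_k > length(fractions)) {
    abort(sprintf(
      "`top_k` (%d) exceeds the number of fractions (%d).",
      top_k, length(fractions)
    ))
  }
  sum(sort(fractions, decreasing = TRUE)[seq_len(top_k)])
}

#' Rank genes by their loading on one eigengene pattern
#'
#' Sorts the oriented loading column of U for the requested pattern in
#' descending order and keeps the top `top_n` genes — the genes whose
#' expression most closely follows that temporal pattern. Ties are broken
#' lexicographically by gene ID so the ranking is deterministic.
#'
#' @param fit An [eigen_decompose()] result.
#' @param pattern Pattern index, 1-based (1 = most significant eigengene).
#' @param top_n Number of genes to keep (default 500, the conventional
#'   selection size for downstream enrichment).
#' @return A tibble with columns `rank`, `gene_id`, `loading`, at most
#'   `top_n` rows.
#' @export
#' @examples
#' sim <- simulate_expression(n_genes = 200, n_timepoints = 6, seed = 1)
#' fit <- eigen_decompose(sim$expression)
#' rank_genes(fit, pattern = 2, top_n = 10)
rank_genes <- function(fit, pattern, top_n = 500) {
  if (!inherits(fit, "eigengene_fit")) {
    abort("`fit` must be an `eigengene_fit` from eigen_decompose().")
  }
  pattern <- check_count(pattern, "pattern", min = 1L)
  if (pattern > ncol(fit$loadings)) {
    abort(sprintf(
      "`pattern` (%d) exceeds the number of patterns (%d).",
      pattern, ncol(fit$loadings)
    ))
  }
  top_n <- check_count(top_n, "top_n", min = 1L)
  if (top_n > nrow(fit$loadings)) {
    abort(sprintf(
      "`top_n` (%d) exceeds the gene count (%d).",
      top_n, nrow(fit$loadings)
    ))
  }
  loading <- fit$loadings[, pattern]
  ord <- order(-loading, names(loading), method = "radix")
  keep <- ord[seq_len(top_n)]
  tibble(
    rank = seq_len(top_n),
    gene_id = names(loading)[keep],
    loading = unname(loading[keep])
  )
}

#' @export
print.eigengene_fit <- function(x, ...) {
  cat(sprintf(
    "<eigengene_fit> %d genes x %d timepoints (transform = %s, center = %s)\n",
    nrow(x$loadings), ncol(x$eigengenes), x$transform, x$center
  ))
  top3 <- cumulative_fraction(x$fractions, min(3L, length(x$fractions)))
  cat(sprintf(
    "  %d eigengene patterns; entropy d = %.3f; top-3 fraction = %.1f%%\n",
    length(x$singular_values), x$entropy, 100 * top3
  ))
  invisible(x)
}

#' Tidy an eigengene decomposition
#'
#' @param x An `eigengene_fit`.
#' @param what Which component to return in long form: `"fractions"` (one row
#'   per pattern with singular value, fraction and cumulative fraction),
#'   `"eigengenes"` (pattern x stage values), or `"loadings"`
#'   (gene x pattern loadings).
#' @param ... Unused.
#' @return A tibble.
#' @method tidy eigengene_fit
#' @export
tidy.eigengene_fit <- function(x, what = c("fractions", "eigengenes", "loadings"),
                               ...) {
  what <- arg_match(what)
  switch(what,
    fractions = tibble(
      pattern = seq_along(x$fractions),
      singular_value = x$singular_values,
      fraction = x$fractions,
      cumulative = cumsum(x$fractions)
    ),
    eigengenes = as_tibble(x$eigengenes, rownames = "pattern") %>%
      tidyr::pivot_longer(-"pattern", names_to = "stage", values_to = "value") %>%
      mutate(
        pattern = as.integer(sub("^pattern", "", .data$pattern)),
        stage = factor(.data$stage, levels = x$stage_labels)
      ),
    loadings = as_tibble(x$loadings, rownames = "gene_id") %>%
      tidyr::pivot_longer(-"gene_id", names_to = "pattern", values_to = "loading") %>%
      mutate(pattern = as.integer(sub("^pattern", "", .data$pattern)))
  )
}

#' One-row summary of an eigengene decomposition
#'
#' @param x An `eigengene_fit`.
#' @param ... Unused.
#' @return A tibble with one row: gene and timepoint counts, pattern count,
#'   entropy, and the cumulative fraction of the top three patterns.
#' @method glance eigengene_fit
#' @export
glance.eigengene_fit <- function(x, ...) {
  tibble(
    n_genes = nrow(x$loadings),
    n_timepoints = ncol(x$eigengenes),
    n_patterns = length(x$singular_values),
    entropy = x$entropy,
    top3_fraction = cumulative_fraction(x$fractions,
                                        min(3L, length(x$fractions)))
  )
}
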