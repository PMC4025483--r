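#' Exact hypergeometric tail test for gene-set over-representation
#'
#' Probability of observing at least `k` annotated genes when drawing `m`
#' genes without replacement from a universe of `M` genes of which `K` carry
#' the annotation:
#' \deqn{P(X \ge k) = \sum_{i=k}^{\min(K, m)} \frac{\binom{K}{i}\binom{M-K}{m-i}}{\binom{M}{m}}}
#' Terms with `i > K` or `m - i > M - K` are outside the support and
#' contribute zero. Each term is evaluated in log space via log-gamma
#' (`lchoose`) and accumulated with a log-sum-exp, so p-values far below the
#' double underflow of a naive product (e.g. ~1e-20) are computed at full
#' relative precision.
#'
#' @param M Universe size (e.g. all genes in the dataset).
#' @param K Number of annotated genes in the universe (catalog size).
#' @param m Selection size (number of genes drawn, e.g. a top-500 list).
#' @param k Observed overlap between the selection and the catalog.
#' @return A one-row tibble with columns `M`, `K`, `m`, `k`, `p_value`
#'   (clamped to (0, 1\]) and `log10_p` (unclamped, exact in log space).
#' @export
#' @examples
#' hypergeom_tail(M = 17000, K = 1228, m = 500, k = 99)
hypergeom_tail <- function(M, K, m, k) {
  M <- check_count(M, "M", min = 0L)
  K <- check_count(K, "K", min = 0L)
  m <- check_count(m, "m", min = 0L)
  k <- check_count(k, "k", min = 0L)
  if (K > M) abort(sprintf("Constraint violated: K (%d) must be <= M (%d).", K, M))
  if (m > M) abort(sprintf("Constraint violated: m (%d) must be <= M (%d).", m, M))
  if (k > m) abort(sprintf("Constraint violated: k (%d) must be <= m (%d).", k, m))
  if (k > K) abort(sprintf("Constraint violated: k (%d) must be <= K (%d).", k, K))

  if (k == 0L) {
    # the sum runs over the whole support, which carries total mass 1
    return(tibble(M = M, K = K, m = m, k = k, p_value = 1, log10_p = 0))
  }

  i <- seq.int(k, min(K, m))
  # drop out-of-support terms (m - i > M - K)
  i <- i[m - i <= M - K]
  if (length(i) == 0L) {
    # empty tail can only arise at k beyond the support upper end, which the
    # constraints above exclude; guard anyway
    return(tibble(M = M, K = K, m = m, k = k, p_value = 0, log10_p = -Inf))
  }
  log_terms <- lchoose(K, i) + lchoose(M - K, m - i) - lchoose(M, m)
  peak <- max(log_terms)
  log_p <- peak + log(sum(exp(log_terms - peak)))
  log_p <- min(log_p, 0) # roundoff guard: a probability cannot exceed 1
  tibble(
    M = M, K = K, m = m, k = k,
    p_value = min(max(exp(log_p), .Machine$double.xmin), 1),
    log10_p = log_p / log(10)
  )
}

#' Build an annotation catalog
#'
#' @param universe Character vector of all gene IDs under consideration
#'   (size `M`).
#' @param annotated Character vector of annotated gene IDs; must be a subset
#'   of `universe` (size `K`).
#' @param label Free-text label for the catalog (e.g. `"metabolic genes"`).
#' @return A list of class `annotation_catalog` with `universe`, `annotated`,
#'   `label`.
#' @export
annotation_catalog <- function(universe, annotated, label = "annotated") {
  universe <- as.character(universe)
  annotated <- as.character(annotated)
  if (anyDuplicated(universe) > 0L) abort("`universe` must not contain duplicates.")
  if (anyDuplicated(annotated) > 0L) abort("`annotated` must not contain duplicates.")
  outside <- setdiff(annotated, universe)
  if (length(outside) > 0L) {
    abort(sprintf(
      "%d annotated gene(s) are not in the universe (e.g. %s).",
      length(outside), paste(head(outside, 3L), collapse = ", ")
    ))
  }
  structure(
    list(universe = universe, annotated = annotated, label = label),
    class = "annotation_catalog"
  )
}

#' @export
print.annotation_catalog <- function(x, ...) {
  cat(sprintf(
    "<annotation_catalog> '%s': %d annotated of %d genes\n",
    x$label, length(x$annotated), length(x$universe)
  ))
  invisible(x)
}

#' Test a gene selection for catalog over-representation
#'
#' Counts how many genes of a selection (for example the top-500 list from
#' [rank_genes()]) carry an annotation and computes the hypergeometric tail
#' probability of an overlap at least that large. Selected genes that are not
#' in the catalog's universe are dropped with a warning before counting.
#'
#' @param selection Character vector of gene IDs, or a tibble with a
#'   `gene_id` column (as returned by [rank_genes()]).
#' @param catalog An [annotation_catalog()].
#' @return A one-row tibble as from [hypergeom_tail()], plus a `label`
#'   column.
#' @export
#' @examples
#' cat <- annotation_catalog(letters, letters[1:6], "vowel-ish")
#' enrich(c("a", "b", "c", "z"), cat)
enrich <- function(selection, catalog) {
  if (!inherits(catalog, "annotation_catalog")) {
    abort("`catalog` must be an annotation_catalog().")
  }
  if (is.data.frame(selection)) {
    require_columns(selection, "gene_id", "`selection`")
    selection <- selection$gene_id
  }
  selection <- as.character(selection)
  selection <- unique(selection)
  outside <- setdiff(selection, catalog$universe)
  if (length(outside) > 0L) {
    warn(sprintf(
      "Dropping %d selected gene(s) not present in the universe.",
      length(outside)
    ))
    selection <- setdiff(selection, outside)
  }
  if (length(selection) == 0L) {
    abort("Selection is empty after restricting to the universe.")
  }
  res <- hypergeom_tail(
    M = length(catalog$universe),
    K = length(catalog$annotated),
    m = length(selection),
    k = length(intersect(selection, catalog$annotated))
  )
  mutate(res, label = catalog$label)
}

#' Read an annotation catalog from a text file
#'
#' Accepts either one gene ID per line, or a two-column tab-separated file
#' (gene ID, label) with no header; in the two-column form the label column is
#' ignored for membership and the file's most common label is used as the
#' catalog label unless `label` is given.
#'
#' @param path Path to the gene-list file.
#' @param universe Character vector of all genes (the enrichment universe).
#' @param label Optional catalog label.
#' @return An [annotation_catalog()]. Genes in the file but absent from
#'   `universe` are dropped with a warning.
#' @export
read_annotation_catalog <- function(path, universe, label = NULL) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  genes <- vapply(parts, `[[`, character(1), 1L)
  file_labels <- vapply(parts, function(p) if (length(p) > 1L) p[[2L]] else NA_character_,
                        character(1))
  if (is.null(label)) {
    label <- if (all(is.na(file_labels))) basename(path) else
      names(sort(table(file_labels), decreasing = TRUE))[1L]
  }
  genes <- unique(genes)
  outside <- setdiff(genes, universe)
  if (length(outside) > 0L) {
    warn(sprintf(
      "Dropping %d catalog gene(s) not present in the universe.",
      length(outside)
    ))
    genes <- setdiff(genes, outside)
  }
  annotation_catalog(universe, genes, label)
}
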