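#' Validate a genes-by-timepoints expression table
#'
#' An expression table holds nonnegative abundances (e.g. RPKM-scale RNA-seq
#' quantifications) for genes in rows and ordered developmental stages in
#' columns. The first column must hold unique gene identifiers; every other
#' column is one timepoint, in developmental order.
#'
#' @param data A data frame: first column gene IDs (character), remaining
#'   columns numeric abundances, one per ordered timepoint.
#' @param require_tall If `TRUE` (the default for decomposition), require at
#'   least as many genes as timepoints so the thin decomposition is full.
#'
#' @return A tibble with the first column named `gene_id`, invisibly checked:
#'   unique gene IDs, at least 2 timepoints, all values finite and
#'   nonnegative.
#' @export
#' @examples
#' tab <- tibble::tibble(
#'   gene_id = c("a", "b", "c"),
#'   `0-2h` = c(1, 2, 3), `2-4h` = c(1, 0, 6)
#' )
#' as_expression_matrix(tab)
as_expression_matrix <- function(data, require_tall = FALSE) {
  if (!is.data.frame(data)) {
    abort("`data` must be a data frame (first column gene IDs).")
  }
  if (ncol(data) < 3L) {
    abort("Expression table needs a gene-ID column plus at least 2 timepoints.")
  }
  data <- as_tibble(data)
  names(data)[1L] <- "gene_id"
  data$gene_id <- as.character(data$gene_id)
  if (anyDuplicated(data$gene_id) > 0L) {
    dup <- unique(data$gene_id[duplicated(data$gene_id)])
    abort(sprintf(
      "Duplicate gene IDs are not allowed (e.g. %s).",
      paste(head(dup, 3L), collapse = ", ")
    ))
  }
  vals <- as.matrix(data[, -1L, drop = FALSE])
  if (!is.numeric(vals)) {
    abort("All timepoint columns must be numeric.")
  }
  if (any(!is.finite(vals))) {
    abort("Expression values must be finite (no NA/NaN/Inf).")
  }
  if (any(vals < 0)) {
    abort("Expression values must be nonnegative.")
  }
  if (require_tall && nrow(vals) < ncol(vals)) {
    abort(sprintf(
      "Matrix has fewer genes (%d) than timepoints (%d); the thin decomposition needs at least as many genes as timepoints.",
      nrow(vals), ncol(vals)
    ))
  }
  data
}

# Numeric matrix view of a validated expression table, gene IDs as rownames.
expression_values <- function(data) {
  m <- as.matrix(data[, -1L, drop = FALSE])
  rownames(m) <- data$gene_id
  m
}

#' Read / write an expression table
#'
#' Tab-separated by default; files ending in `.csv` are read and written
#' comma-separated. The header row carries the stage labels and the first
#' column the gene IDs.
#'
#' @param path File path; the extension selects the dialect.
#' @return `read_expression_matrix()` returns a validated tibble (see
#'   [as_expression_matrix()]).
#' @export
read_expression_matrix <- function(path) {
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  data <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                            progress = FALSE)
  as_expression_matrix(data)
}

#' @rdname read_expression_matrix
#' @param data A data frame as accepted by [as_expression_matrix()].
#' @export
write_expression_matrix <- function(data, path) {
  data <- as_expression_matrix(data)
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  readr::write_delim(data, path, delim = delim)
  invisible(path)
}
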