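# Small fixtures built in code.

# Expression table from an explicit numeric matrix.
expr_table <- function(mat, gene_ids = sprintf("g%02d", seq_len(nrow(mat))),
                       stages = sprintf("t%02d", seq_len(ncol(mat)))) {
  tibble::as_tibble(stats::setNames(
    c(list(gene_ids), lapply(seq_len(ncol(mat)), function(j) mat[, j])),
    c("gene_id", stages)
  ))
}

# Long-format peak table from a metabolite x timepoint matrix of true values,
# one replicate set per `reps`, internal standard fixed at `std`.
peak_table <- function(values, reps = 1, std = 1,
                       standard = "D4-succinate") {
  mets <- rownames(values)
  tps <- colnames(values)
  rows <- list()
  for (tp in tps) {
    for (r in seq_len(reps)) {
      sid <- sprintf("S_%s_r%d", tp, r)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        sample_id = sid, timepoint = tp, replicate = r,
        metabolite = c(mets, standard),
        peak_area = unname(c(values[, tp], std))
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  out$timepoint <- factor(out$timepoint, levels = tps)
  out
}
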