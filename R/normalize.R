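#' MAXMIN normalization
#'
#' Rescales every gene row to `[0, 1]` by `(x - min) / (max - min)`, computed
#' per gene across its samples. This is the standard per-gene min-max rescaling
#' used before RBM training, which expects visible inputs in the unit interval.
#' A constant row has zero range, so it is mapped to all zeros (the "no
#' signal" encoding) with a warning; for every non-constant row the minimum is
#' exactly 0 and the maximum exactly 1, and within-row ordering is preserved.
#' The operation is idempotent.
#'
#' @param x An `expr_tbl`, or a numeric matrix (genes in rows).
#' @return The same type as `x`, with every row rescaled.
#' @examples
#' maxmin_normalize(matrix(c(1, 3, 2), 1, dimnames = list("g1", c("a", "b", "c"))))
#' @export
maxmin_normalize <- function(x) {
  if (is.matrix(x)) return(maxmin_rows(x))
  stopifnot(inherits(x, "data.frame"))
  m <- maxmin_rows(expr_values(x))
  out <- dplyr::bind_cols(tibble::tibble(gene_id = expr_genes(x)),
                          tibble::as_tibble(m, .name_repair = "minimal"))
  as_expr_tbl(out, phenotype = expr_phenotype(x))
}

maxmin_rows <- function(m) {
  storage.mode(m) <- "double"
  rng <- apply(m, 1L, range)
  span <- rng[2L, ] - rng[1L, ]
  flat <- span == 0
  if (any(flat)) {
    warn(sprintf("%d constant gene row(s) normalized to all zeros: %s",
                 sum(flat), paste(head(rownames(m)[flat], 5L), collapse = ", ")))
  }
  out <- (m - rng[1L, ]) / ifelse(flat, 1, span)
  out[flat, ] <- 0
  out
}
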