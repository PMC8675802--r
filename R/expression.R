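#' Expression tables
#'
#' `rbmgrn` carries expression data as a tibble with one row per gene: the
#' first column, `gene_id`, holds unique gene identifiers and every remaining
#' column holds the (numeric) intensities of one sample. Sample phenotype
#' labels (e.g. `"normal"` / `"diseased"`), when known, live in a `phenotype`
#' attribute: a character vector named by sample id. `as_expr_tbl()` validates
#' a data frame into this shape; the accessors below pull the pieces out.
#'
#' @param x A data frame whose first column is `gene_id` (or a numeric matrix
#'   with rownames as gene ids and colnames as sample ids).
#' @param phenotype Optional character vector of group labels, either named by
#'   sample id or in sample-column order.
#' @return `as_expr_tbl()` returns a tibble of class `expr_tbl`;
#'   `expr_values()` a numeric genes-by-samples matrix with dimnames;
#'   `expr_genes()` / `expr_samples()` character vectors;
#'   `expr_phenotype()` the named label vector or `NULL`.
#' @examples
#' x <- as_expr_tbl(tibble::tibble(gene_id = c("g1", "g2"), s1 = c(1, 2), s2 = c(3, 4)))
#' expr_values(x)
#' @export
as_expr_tbl <- function(x, phenotype = NULL) {
  if (is.matrix(x)) {
    if (is.null(rownames(x)) || is.null(colnames(x))) {
      abort("A matrix input needs rownames (gene ids) and colnames (sample ids).")
    }
    x <- dplyr::bind_cols(tibble::tibble(gene_id = rownames(x)),
                          tibble::as_tibble(x, .name_repair = "minimal"))
  }
  x <- tibble::as_tibble(x)
  if (ncol(x) < 2L) abort("An expression table needs a gene id column and at least one sample column.")
  names(x)[1L] <- "gene_id"
  x$gene_id <- as.character(x$gene_id)
  if (anyDuplicated(x$gene_id)) {
    dup <- unique(x$gene_id[duplicated(x$gene_id)])
    abort(sprintf("Duplicate gene id(s): %s", paste(dup, collapse = ", ")))
  }
  if (anyDuplicated(names(x)[-1L])) abort("Sample ids must be unique.")
  for (j in seq(2L, ncol(x))) {
    col <- x[[j]]
    if (!is.numeric(col)) abort(sprintf("Sample column '%s' is not numeric.", names(x)[j]))
    if (anyNA(col)) {
      abort(sprintf("Missing value in column '%s' (gene '%s').",
                    names(x)[j], x$gene_id[which(is.na(col))[1L]]))
    }
  }
  samples <- names(x)[-1L]
  if (!is.null(phenotype)) {
    phenotype <- as.character(phenotype) |> setNames(names(phenotype) %||% samples)
    missing <- setdiff(samples, names(phenotype))
    if (length(missing)) {
      abort(sprintf("Phenotype labels missing for sample(s): %s", paste(missing, collapse = ", ")))
    }
    phenotype <- phenotype[samples]
  }
  structure(x, phenotype = phenotype, class = c("expr_tbl", class(x)))
}

#' @rdname as_expr_tbl
#' @export
expr_values <- function(x) {
  stopifnot(inherits(x, "data.frame"))
  m <- as.matrix(x[, -1L, drop = FALSE])
  rownames(m) <- x[[1L]]
  storage.mode(m) <- "double"
  m
}

#' @rdname as_expr_tbl
#' @export
expr_genes <- function(x) as.character(x[[1L]])

#' @rdname as_expr_tbl
#' @export
expr_samples <- function(x) names(x)[-1L]

#' @rdname as_expr_tbl
#' @export
expr_phenotype <- function(x) attr(x, "phenotype", exact = TRUE)

#' Select genes from an expression table
#'
#' Returns the submatrix of `x` restricted to `keep`, with rows reordered to
#' follow `keep` exactly. Used to carry a ranked-and-matched gene subset from
#' one data set over to another.
#'
#' @param x An `expr_tbl`.
#' @param keep Character vector of gene ids; every id must be present in `x`.
#' @return An `expr_tbl` with `length(keep)` rows in the order of `keep`.
#' @export
select_genes <- function(x, keep) {
  keep <- as.character(keep)
  missing <- setdiff(keep, expr_genes(x))
  if (length(missing)) {
    abort(sprintf("Gene id(s) not present: %s", paste(missing, collapse = ", ")))
  }
  out <- x[match(keep, expr_genes(x)), , drop = FALSE]
  as_expr_tbl(out, phenotype = expr_phenotype(x))
}

#' Read a delimited expression table
#'
#' Expects gene ids in the first column and sample ids in the first row. An
#' optional second header row whose first field is `#group` carries one
#' phenotype label per sample. Any non-numeric cell or duplicated gene id is a
#' format error naming the offending location.
#'
#' @param path File path.
#' @param delim Field delimiter; tab by default.
#' @return An `expr_tbl` (with phenotype labels if a `#group` row is present).
#' @export
read_expression_table <- function(path, delim = "\t") {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L) abort(sprintf("'%s' is not an expression table (need a header and at least one gene row).", path))
  split1 <- function(l) strsplit(l, delim, fixed = TRUE)[[1L]]
  header <- split1(lines[[1L]])
  samples <- header[-1L]
  phenotype <- NULL
  body_start <- 2L
  second <- split1(lines[[2L]])
  if (identical(second[[1L]], "#group")) {
    if (length(second) - 1L != length(samples)) {
      abort("The #group row must carry one label per sample.")
    }
    phenotype <- setNames(second[-1L], samples)
    body_start <- 3L
  }
  if (body_start > length(lines)) abort(sprintf("'%s' has no gene rows.", path))
  rows <- lapply(lines[seq(body_start, length(lines))], split1)
  gene_ids <- vapply(rows, `[[`, character(1L), 1L)
  vals <- matrix(NA_real_, nrow = length(rows), ncol = length(samples),
                 dimnames = list(gene_ids, samples))
  for (i in seq_along(rows)) {
    fields <- rows[[i]][-1L]
    if (length(fields) != length(samples)) {
      abort(sprintf("Row for gene '%s' has %d value(s); expected %d.",
                    gene_ids[i], length(fields), length(samples)))
    }
    v <- suppressWarnings(as.numeric(fields))
    if (anyNA(v)) {
      j <- which(is.na(v))[1L]
      abort(sprintf("Non-numeric cell '%s' at gene '%s', sample '%s'.",
                    fields[j], gene_ids[i], samples[j]))
    }
    vals[i, ] <- v
  }
  out <- as_expr_tbl(vals, phenotype = phenotype)
  inform(sprintf("Read %d genes x %d samples from %s.", nrow(out), length(samples), path))
  out
}

#' Write an expression table
#'
#' Emits the dialect read by [read_expression_table()]: sample-id header,
#' optional `#group` phenotype row, one row per gene. Values are printed at
#' full double precision so a write-read round trip is exact.
#'
#' @param x An `expr_tbl`.
#' @param path Output path.
#' @param delim Field delimiter.
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(x, path, delim = "\t") {
  samples <- expr_samples(x)
  lines <- paste(c("gene_id", samples), collapse = delim)
  ph <- expr_phenotype(x)
  if (!is.null(ph)) {
    lines <- c(lines, paste(c("#group", unname(ph[samples])), collapse = delim))
  }
  m <- expr_values(x)
  body <- vapply(seq_len(nrow(m)), function(i) {
    paste(c(rownames(m)[i], sprintf("%.17g", m[i, ])), collapse = delim)
  }, character(1L))
  readr::write_lines(c(lines, body), path)
  invisible(path)
}
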