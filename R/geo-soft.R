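#' Read a GEO GDS SOFT dataset file
#'
#' Minimal reader for the plain-text GDS SOFT dialect: metadata lines starting
#' with `^`, `!` or `#`, then a table delimited by tabs whose first two columns
#' are `ID_REF` and `IDENTIFIER` followed by one column per sample (GSM ids).
#' `!subset_sample_id` / `!subset_description` blocks, when present, populate
#' the phenotype labels. Gene ids are taken from `IDENTIFIER`, falling back to
#' `ID_REF` where the identifier is blank; duplicated identifiers are
#' disambiguated by appending the `ID_REF`. Rows containing any non-numeric
#' value (e.g. `null`) are dropped with a message reporting the count.
#'
#' Only the GDS dataset dialect is supported; GSE/GPL family files are not.
#'
#' @param path Path to a SOFT file.
#' @return An `expr_tbl`, with phenotype labels when subset blocks exist.
#' @export
read_geo_soft_gds <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  lines <- readr::read_lines(path)

  # phenotype from subset blocks: pairs of !subset_description / !subset_sample_id
  subset_desc <- NA_character_
  phenotype <- character(0)
  for (l in lines) {
    if (startsWith(l, "!subset_description")) {
      subset_desc <- trimws(sub("^!subset_description\\s*=\\s*", "", l))
    } else if (startsWith(l, "!subset_sample_id")) {
      ids <- trimws(strsplit(sub("^!subset_sample_id\\s*=\\s*", "", l), ",")[[1L]])
      phenotype[ids] <- if (is.na(subset_desc)) "subset" else subset_desc
    }
  }

  is_meta <- startsWith(lines, "!") | startsWith(lines, "#") | startsWith(lines, "^")
  tbl_lines <- lines[!is_meta & nzchar(trimws(lines))]
  if (length(tbl_lines) < 2L) abort(sprintf("'%s' has no SOFT table block.", path))
  header <- strsplit(tbl_lines[[1L]], "\t", fixed = TRUE)[[1L]]
  if (length(header) < 3L || header[[1L]] != "ID_REF") {
    abort(sprintf("'%s' has no SOFT table block (expected an ID_REF header).", path))
  }
  samples <- header[-(1:2)]

  rows <- strsplit(tbl_lines[-1L], "\t", fixed = TRUE)
  id_ref <- vapply(rows, `[[`, character(1L), 1L)
  ident <- vapply(rows, function(r) if (length(r) >= 2L) r[[2L]] else "", character(1L))
  gene_ids <- ifelse(nzchar(trimws(ident)), trimws(ident), id_ref)
  gene_ids[duplicated(gene_ids) | duplicated(gene_ids, fromLast = TRUE)] <-
    paste0(gene_ids, ".", id_ref)[duplicated(gene_ids) | duplicated(gene_ids, fromLast = TRUE)]

  vals <- t(vapply(rows, function(r) {
    suppressWarnings(as.numeric(r[-(1:2)]))[seq_along(samples)]
  }, numeric(length(samples))))
  keep <- !apply(vals, 1L, anyNA)
  if (any(!keep)) {
    inform(sprintf("Dropped %d row(s) with non-numeric values.", sum(!keep)))
  }
  vals <- vals[keep, , drop = FALSE]
  dimnames(vals) <- list(gene_ids[keep], samples)

  if (length(phenotype)) {
    unknown <- setdiff(names(phenotype), samples)
    if (length(unknown)) {
      warn(sprintf("Subset sample id(s) absent from the table, ignored: %s",
                   paste(unknown, collapse = ", ")))
      phenotype <- phenotype[setdiff(names(phenotype), unknown)]
    }
    full <- setNames(rep(NA_character_, length(samples)), samples)
    full[names(phenotype)] <- phenotype
    phenotype <- full[!is.na(full)]
    if (!length(phenotype)) phenotype <- NULL
  } else {
    phenotype <- NULL
  }

  out <- x <- tibble::as_tibble(as.data.frame(vals), .name_repair = "minimal")
  out <- dplyr::bind_cols(tibble::tibble(gene_id = rownames(vals)), out)
  out <- tibble::as_tibble(out)
  if (!is.null(phenotype) && length(phenotype) < length(samples)) {
    # labels must cover every sample to be attached; keep partial coverage as full
    # vector with "unassigned" for unlabeled samples
    lab <- setNames(rep("unassigned", length(samples)), samples)
    lab[names(phenotype)] <- phenotype
    phenotype <- lab
  }
  as_expr_tbl(out, phenotype = phenotype)
}
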