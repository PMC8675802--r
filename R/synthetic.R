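#' Worked-example fixture tables
#'
#' The small worked-example data sets used throughout the documentation and
#' tests, stored verbatim: `table1` (5 genes x 6 samples, raw log-scale
#' intensities), `table2` (its MAXMIN-normalized counterpart, printed to 4
#' decimal places), `table3` and `table4` (4 x 4 interaction-strength matrices
#' before and after thresholding was illustrated; they differ in the
#' Gene3/Gene4 cell — 0.7 versus 0.6843 — and the threshold walk-through is
#' only consistent with `table4`), and `table5` (raw expression of two genes
#' across 9 samples, the direction-classifier example).
#'
#' @return A named list of matrices, freshly constructed on each call.
#' @examples
#' fixture_tables()$table1["Gene2", "Sample3"]
#' @export
fixture_tables <- function() {
  samples6 <- paste0("Sample", 1:6)
  genes5 <- paste0("Gene", 1:5)
  table1 <- matrix(c(
    5.27055, 5.07397, 5.20949, 5.25106, 5.38327, 5.13528,
    7.41519, 7.11951, 8.54414, 7.73497, 7.70082, 8.04083,
    5.04245, 5.01335, 5.15868, 4.58296, 5.15520, 4.58029,
    5.89670, 5.82747, 6.10051, 5.71561, 6.25209, 5.96030,
    4.68734, 4.62737, 4.71932, 4.77644, 4.63229, 4.29907
  ), nrow = 5, byrow = TRUE, dimnames = list(genes5, samples6))
  table2 <- matrix(c(
    0.6355, 0,      0.4381, 0.5725, 1,      0.1982,
    0.2075, 0,      1,      0.4320, 0.4080, 0.6467,
    0.7990, 0.7487, 1,      0.0046, 0.9939, 0,
    0.3375, 0.2085, 0.7174, 0,      1,      0.4561,
    0.8133, 0.6877, 0.8803, 1,      0.6980, 0
  ), nrow = 5, byrow = TRUE, dimnames = list(genes5, samples6))
  genes4 <- paste0("Gene", 1:4)
  table3 <- matrix(c(
    NA,     0.765, 0.772, 0.698,
    0.779,  NA,    0.73,  0.721,
    0.77,   0.733, NA,    0.7,
    0.6695, 0.736, 0.682, NA
  ), nrow = 4, byrow = TRUE, dimnames = list(genes4, genes4))
  table4 <- table3
  table4["Gene3", "Gene4"] <- 0.6843
  table5 <- matrix(c(
    4.3078, 4.5863, 4.8488, 4.7809, 4.1483, 3.8997, 4.2633, 4.2199, 4.4515,
    7.0182, 6.6068, 8.3893, 8.1416, 7.5879, 6.7963, 8.4705, 7.2029, 5.5523
  ), nrow = 2, byrow = TRUE,
  dimnames = list(c("Gene1", "Gene3"), paste0("Sample", 1:9)))
  list(table1 = table1, table2 = table2, table3 = table3,
       table4 = table4, table5 = table5)
}

#' Candidate pairs implied by a strength matrix
#'
#' Rewrites a square strength matrix (such as `table4` from
#' [fixture_tables()]) into the candidate-pair form [filter_interactions()]
#' consumes: for each unordered pair `(i, j)` with `i < j`, `strength_a` is
#' the `[i, j]` cell and `strength_b` the `[j, i]` cell.
#'
#' @param m Square numeric matrix with gene ids as dimnames; the diagonal is
#'   ignored.
#' @return A tibble with `gene_a`, `gene_b`, `strength_a`, `strength_b`,
#'   `converged = TRUE`.
#' @export
strength_matrix_candidates <- function(m) {
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  ids <- rownames(m)
  pairs <- combn(seq_len(nrow(m)), 2L)
  tibble::tibble(
    gene_a = ids[pairs[1L, ]], gene_b = ids[pairs[2L, ]],
    strength_a = m[cbind(pairs[1L, ], pairs[2L, ])],
    strength_b = m[cbind(pairs[2L, ], pairs[1L, ])],
    converged = TRUE
  )
}

#' Specification for a synthetic expression matrix
#'
#' Describes a genes-by-samples matrix of log-scale intensities with optional
#' planted regulator-to-target structure. Unplanted genes draw each sample
#' independently from `Normal(baseline_mu + gene offset, baseline_sd)`; each
#' planted target is `effect * (regulator - mean(regulator))` plus its own
#' baseline plus `Normal(0, noise_sd)` noise, giving the pair a controlled
#' co-expression signal. Defaults (`baseline_mu = 7`, `baseline_sd = 1.2`)
#' mimic the 4-9 log-intensity range typical of microarray data; per-gene
#' offsets are drawn once from `Normal(0, 1)` so genes differ in baseline the
#' way probes do.
#'
#' @param n_genes,n_samples Matrix dimensions.
#' @param planted_pairs A list of lists, each with `regulator`, `target`
#'   (gene indices), `effect` and `noise_sd`.
#' @param baseline_mu,baseline_sd Baseline intensity model.
#' @param seed Integer seed; generation is fully reproducible.
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_genes, n_samples, planted_pairs = list(),
                           baseline_mu = 7, baseline_sd = 1.2, seed = 1L) {
  stopifnot(n_genes >= 1, n_samples >= 1, baseline_sd > 0)
  planted <- unique(unlist(lapply(planted_pairs, function(p) c(p$regulator, p$target))))
  if (length(planted)) {
    if (any(planted < 1 | planted > n_genes)) abort("Planted gene index out of range.")
    targets <- vapply(planted_pairs, function(p) p$target, numeric(1L))
    if (anyDuplicated(targets)) abort("Each target index may be planted at most once.")
  }
  structure(list(n_genes = as.integer(n_genes), n_samples = as.integer(n_samples),
                 planted_pairs = planted_pairs, baseline_mu = baseline_mu,
                 baseline_sd = baseline_sd, seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a synthetic expression matrix
#'
#' @param spec A [synthetic_spec()].
#' @return An `expr_tbl` with genes `g01`, `g02`, ...
#' @examples
#' sp <- synthetic_spec(4, 10, list(list(regulator = 1, target = 2,
#'                                       effect = 1, noise_sd = 0.2)))
#' generate_expression(sp)
#' @export
generate_expression <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  withr::with_seed(spec$seed, {
    g <- spec$n_genes; n <- spec$n_samples
    ids <- sprintf("g%02d", seq_len(g))
    offsets <- rnorm(g)
    m <- matrix(rnorm(g * n, mean = spec$baseline_mu, sd = spec$baseline_sd),
                g, n) + offsets
    dimnames(m) <- list(ids, sprintf("s%02d", seq_len(n)))
    for (p in spec$planted_pairs) {
      reg <- m[p$regulator, ]
      m[p$target, ] <- p$effect * (reg - mean(reg)) +
        spec$baseline_mu + offsets[p$target] + rnorm(n, sd = p$noise_sd)
    }
    as_expr_tbl(m)
  })
}

#' Generate a matched pair of condition matrices
#'
#' Produces two expression matrices over the SAME gene ids with independently
#' specified planted structure — a stand-in for paired normal/diseased (or
#' adenoma/carcinoma) inputs when exercising network differencing. With
#' `shared_seed = TRUE`, `spec_b`'s seed is replaced by `spec_a`'s, so
#' identical specs then yield identical matrices.
#'
#' @param spec_a,spec_b Two [synthetic_spec()]s with equal `n_genes`.
#' @param shared_seed Reuse `spec_a$seed` for `spec_b`.
#' @return A named list of two `expr_tbl`s (`a`, `b`).
#' @export
generate_condition_pair <- function(spec_a, spec_b, shared_seed = FALSE) {
  if (spec_a$n_genes != spec_b$n_genes) {
    abort("Both specs must declare the same number of genes.")
  }
  if (shared_seed) spec_b$seed <- spec_a$seed
  list(a = generate_expression(spec_a), b = generate_expression(spec_b))
}
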