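#' Filter interaction candidates with the theta rule
#'
#' A candidate pair is accepted as an interaction when it converged AND its two
#' interaction strengths agree to within `theta` (inclusive comparison:
#' `|strength_a - strength_b| <= theta`). The conventional range for `theta`
#' is 0.004 to 0.016; the retained set is monotone non-decreasing in `theta`.
#'
#' @param candidates A data frame with columns `gene_a`, `gene_b`,
#'   `strength_a`, `strength_b` and (optionally) `converged`; rows with a
#'   missing strength never pass. An absent `converged` column is treated as
#'   all-converged, which is how the worked strength-table examples are run.
#' @param theta Positive acceptance threshold.
#' @return The accepted subset of `candidates`, same columns.
#' @export
filter_interactions <- function(candidates, theta = 0.006) {
  if (!is.numeric(theta) || length(theta) != 1L || theta <= 0) {
    abort("`theta` must be a single positive number.")
  }
  conv <- if ("converged" %in% names(candidates)) candidates$converged else TRUE
  gap <- abs(candidates$strength_a - candidates$strength_b)
  dplyr::filter(tibble::as_tibble(candidates), conv, !is.na(gap), gap <= theta)
}

#' Count accepted edges across a threshold sweep
#'
#' Evaluates `nrow(filter_interactions(candidates, theta))` at each threshold;
#' the counts are non-decreasing because the filter is monotone in `theta`.
#'
#' @inheritParams filter_interactions
#' @param thetas Strictly ascending vector of thresholds.
#' @return A tibble of class `grn_edge_curve` with columns `theta`,
#'   `edge_count`.
#' @export
edges_vs_threshold <- function(candidates, thetas = seq(0.004, 0.016, by = 0.002)) {
  if (is.unsorted(thetas, strictly = TRUE)) abort("`thetas` must be strictly ascending.")
  out <- tibble::tibble(
    theta = as.numeric(thetas),
    edge_count = vapply(thetas, function(t) nrow(filter_interactions(candidates, t)), integer(1L))
  )
  class(out) <- c("grn_edge_curve", class(out))
  out
}

#' Assemble a directed regulatory network from accepted pairs
#'
#' Orients every accepted candidate pair with the Gaussian naive-Bayes rule
#' ([decide_direction()]) applied to the genes' RAW (pre-normalization)
#' expression rows, and carries as edge weight the interaction strength
#' belonging to the regulator's side of the pair.
#'
#' @param candidates Accepted candidates (output of [filter_interactions()]).
#' @param expressions An `expr_tbl` of RAW intensities containing every gene
#'   that appears in `candidates`.
#' @param condition_label Free-text label for the condition (e.g. "normal").
#' @param theta The threshold the candidates were filtered at (recorded).
#' @return An object of class `grn`: node ids, an edge tibble
#'   (`regulator`, `target`, `strength`, `score_forward`, `score_backward`,
#'   `tie`), the condition label and theta.
#' @export
build_network <- function(candidates, expressions, condition_label = "condition",
                          theta = NA_real_) {
  genes <- expr_genes(expressions)
  used <- unique(c(candidates$gene_a, candidates$gene_b))
  missing <- setdiff(used, genes)
  if (length(missing)) {
    abort(sprintf("Gene row(s) missing from `expressions`: %s", paste(missing, collapse = ", ")))
  }
  m <- expr_values(expressions)
  edges <- purrr::map(seq_len(nrow(candidates)), function(i) {
    a <- candidates$gene_a[i]; b <- candidates$gene_b[i]
    dec <- decide_direction(m[a, ], m[b, ], a, b)
    dec$strength <- if (dec$regulator == a) candidates$strength_a[i] else candidates$strength_b[i]
    dec
  })
  edges <- if (length(edges)) {
    dplyr::bind_rows(edges)[, c("regulator", "target", "strength",
                                "score_forward", "score_backward", "tie")]
  } else {
    tibble::tibble(regulator = character(), target = character(),
                   strength = numeric(), score_forward = numeric(),
                   score_backward = numeric(), tie = logical())
  }
  structure(list(nodes = genes, edges = edges,
                 condition_label = condition_label, theta = theta),
            class = "grn")
}

#' @export
print.grn <- function(x, ...) {
  cat(sprintf("<grn> '%s': %d node(s), %d directed edge(s), theta = %s\n",
              x$condition_label, length(x$nodes), nrow(x$edges), format(x$theta)))
  if (nrow(x$edges)) print(x$edges, n = 10)
  invisible(x)
}

#' @export
tidy.grn <- function(x, ...) {
  dplyr::mutate(x$edges, condition = x$condition_label, theta = x$theta)
}

#' @export
glance.grn <- function(x, ...) {
  tibble::tibble(condition = x$condition_label, theta = x$theta,
                 n_nodes = length(x$nodes), n_edges = nrow(x$edges),
                 n_ties = sum(x$edges$tie),
                 mean_strength = mean(x$edges$strength))
}

unordered_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "\r")
}

#' Compare two regulatory networks
#'
#' Partitions the union of unordered edge pairs of two networks (for example
#' normal versus diseased, or adenoma versus carcinoma) into four disjoint
#' classes: present only in `net_x`, only in `net_y`, shared with the same
#' direction, and shared with the direction reversed.
#'
#' @param net_x,net_y Two `grn` objects.
#' @return A list of class `grn_comparison`: tibbles `only_x`, `only_y`,
#'   `shared_same_direction`, `shared_reversed_direction` (each with
#'   `regulator`/`target` as oriented in `net_x` where applicable), and a
#'   one-row `counts` tibble; class sizes sum to the union of pairs.
#' @export
compare_networks <- function(net_x, net_y) {
  stopifnot(inherits(net_x, "grn"), inherits(net_y, "grn"))
  ex <- net_x$edges; ey <- net_y$edges
  kx <- unordered_key(ex$regulator, ex$target)
  ky <- unordered_key(ey$regulator, ey$target)
  pick <- function(e, idx) e[idx, c("regulator", "target", "strength"), drop = FALSE]
  shared_x <- ex[kx %in% ky, , drop = FALSE]
  same <- vapply(seq_len(nrow(shared_x)), function(i) {
    any(ey$regulator == shared_x$regulator[i] & ey$target == shared_x$target[i])
  }, logical(1L))
  out <- list(
    only_x = pick(ex, !(kx %in% ky)),
    only_y = pick(ey, !(ky %in% kx)),
    shared_same_direction = shared_x[same, c("regulator", "target", "strength"), drop = FALSE],
    shared_reversed_direction = shared_x[!same, c("regulator", "target", "strength"), drop = FALSE]
  )
  out$counts <- tibble::tibble(
    only_x = nrow(out$only_x), only_y = nrow(out$only_y),
    shared_same_direction = nrow(out$shared_same_direction),
    shared_reversed_direction = nrow(out$shared_reversed_direction),
    pair_union = length(union(kx, ky))
  )
  structure(out, class = "grn_comparison")
}

#' @export
print.grn_comparison <- function(x, ...) {
  cat("<grn_comparison>\n")
  print(x$counts)
  invisible(x)
}

#' @export
tidy.grn_comparison <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(x$only_x, class = "only_x"),
    dplyr::mutate(x$only_y, class = "only_y"),
    dplyr::mutate(x$shared_same_direction, class = "shared_same_direction"),
    dplyr::mutate(x$shared_reversed_direction, class = "shared_reversed_direction")
  )
}

#' @export
glance.grn_comparison <- function(x, ...) x$counts

#' Convert a network to an igraph object
#'
#' @param net A `grn`.
#' @return A directed `igraph` graph with `strength` and `tie` edge
#'   attributes (`tie` as 0/1, which every graph format can carry); isolated
#'   genes are kept as vertices.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "grn"))
  e <- net$edges[, c("regulator", "target", "strength", "tie")]
  e$tie <- as.integer(e$tie)
  igraph::graph_from_data_frame(e, directed = TRUE, vertices = net$nodes)
}

#' Export a regulatory network
#'
#' Writes the network as an edge-list TSV (columns `regulator`, `target`,
#' `strength`, `tie`, `theta`, `condition`; read back with
#' [read_network_tsv()]), GraphML, or DOT. The graph formats carry `strength`
#' as an edge attribute.
#'
#' @param net A `grn`.
#' @param path Destination file.
#' @param format One of `"tsv"`, `"graphml"`, `"dot"`.
#' @return `path`, invisibly.
#' @export
export_network <- function(net, path, format = c("tsv", "graphml", "dot")) {
  format <- match.arg(format)
  if (format == "tsv") {
    readr::write_tsv(tidy(net)[, c("regulator", "target", "strength", "tie",
                                   "theta", "condition")], path)
  } else {
    igraph::write_graph(as_igraph(net), path, format = format)
  }
  invisible(path)
}

#' Read an edge-list TSV written by [export_network()]
#'
#' @param path Edge-list TSV path.
#' @param nodes Optional full node set (defaults to the genes on the edges).
#' @return A `grn` object.
#' @export
read_network_tsv <- function(path, nodes = NULL) {
  e <- readr::read_tsv(path, show_col_types = FALSE,
                       col_types = readr::cols(
                         regulator = readr::col_character(),
                         target = readr::col_character(),
                         strength = readr::col_double(),
                         tie = readr::col_logical(),
                         theta = readr::col_double(),
                         condition = readr::col_character()))
  structure(list(nodes = nodes %||% sort(unique(c(e$regulator, e$target))),
                 edges = e[, c("regulator", "target", "strength", "tie")],
                 condition_label = if (nrow(e)) e$condition[[1L]] else "condition",
                 theta = if (nrow(e)) e$theta[[1L]] else NA_real_),
            class = "grn")
}
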