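#' Run the full interaction-to-network pipeline
#'
#' Wires the stages together for one or two conditions: read (or accept)
#' expression matrices, optionally rank genes between two phenotype groups and
#' keep the top of the ranking, normalize each gene to `[0, 1]`, train a
#' bridged RBM pair on every unordered gene pair, filter candidates at
#' `theta`, orient accepted pairs with the Gaussian naive-Bayes rule, and
#' write the run artifacts: per-condition candidate TSVs, network exports, an
#' edges-versus-threshold table, a cross-condition comparison (when two
#' conditions are given) and a JSON manifest recording the configuration.
#' Identical inputs, configuration and seed reproduce identical artifacts.
#'
#' @param inputs A named list (names become condition labels) of `expr_tbl`
#'   objects or file paths (delimited tables, or GDS SOFT files when the
#'   first line starts with `^` or `!`). One or two conditions.
#' @param output_dir Directory for run artifacts; created if needed.
#' @param theta Acceptance threshold for [filter_interactions()].
#' @param config An [rbm_config()].
#' @param seed Global seed; per-pair seeds derive from it.
#' @param rank_groups Optional length-2 character vector of phenotype labels;
#'   genes are ranked with [wilcoxon_rank_genes()] on the FIRST condition and
#'   the top `n_top` kept in every condition.
#' @param n_top Number of top-ranked genes to keep (used with `rank_groups`).
#' @param select Optional explicit gene-id vector applied to every condition
#'   (alternative to ranking).
#' @param formats Network export formats, subset of `c("tsv", "graphml",
#'   "dot")`.
#' @param thetas Threshold sweep for the edges-versus-threshold table.
#' @return Invisibly, a list with `networks`, `candidates`, `edge_curves`,
#'   `comparison` (or `NULL`), and `manifest` (path).
#' @export
run_pipeline <- function(inputs, output_dir, theta = 0.006,
                         config = rbm_config(), seed = 1L,
                         rank_groups = NULL, n_top = NULL, select = NULL,
                         formats = "tsv",
                         thetas = seq(0.004, 0.016, by = 0.002)) {
  if (is.null(names(inputs)) || any(!nzchar(names(inputs)))) {
    names(inputs) <- paste0("condition_", seq_along(inputs))
  }
  if (!length(inputs) %in% 1:2) abort("`inputs` must hold one or two conditions.")
  formats <- match.arg(formats, c("tsv", "graphml", "dot"), several.ok = TRUE)
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("Pipeline stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }

  raw <- stage("read", purrr::map(inputs, function(inp) {
    if (inherits(inp, "data.frame")) return(as_expr_tbl(inp, expr_phenotype(inp)))
    first <- readr::read_lines(inp, n_max = 1L)
    if (startsWith(first, "^") || startsWith(first, "!")) read_geo_soft_gds(inp)
    else read_expression_table(inp)
  }))

  if (!is.null(rank_groups)) {
    ranked <- stage("rank", wilcoxon_rank_genes(raw[[1L]], rank_groups[[1L]], rank_groups[[2L]]))
    keep_n <- n_top %||% nrow(ranked)
    select <- head(ranked$gene_id, keep_n)
  }
  if (!is.null(select)) {
    raw <- stage("select", purrr::map(raw, function(x) {
      select_genes(x, intersect(select, expr_genes(x)))
    }))
  }

  normalized <- stage("normalize", purrr::map(raw, maxmin_normalize))

  candidates <- stage("train", purrr::imap(normalized, function(x, label) {
    train_all_pairs(x, config = config, seed = seed)
  }))
  purrr::iwalk(candidates, function(cand, label) {
    readr::write_tsv(tibble::as_tibble(cand),
                     file.path(output_dir, paste0("candidates_", label, ".tsv")))
  })

  edge_curves <- stage("edge_curve", purrr::map(candidates, edges_vs_threshold, thetas = thetas))
  purrr::iwalk(edge_curves, function(ec, label) {
    readr::write_tsv(tibble::as_tibble(ec),
                     file.path(output_dir, paste0("edges_vs_theta_", label, ".tsv")))
  })

  networks <- stage("network", purrr::imap(raw, function(x, label) {
    build_network(filter_interactions(candidates[[label]], theta), x,
                  condition_label = label, theta = theta)
  }))
  purrr::iwalk(networks, function(net, label) {
    for (fmt in formats) {
      ext <- c(tsv = "tsv", graphml = "graphml", dot = "dot")[[fmt]]
      export_network(net, file.path(output_dir, paste0("network_", label, ".", ext)), fmt)
    }
  })

  comparison <- NULL
  if (length(networks) == 2L) {
    comparison <- stage("compare", compare_networks(networks[[1L]], networks[[2L]]))
    jsonlite::write_json(
      list(conditions = names(networks),
           counts = as.list(comparison$counts),
           only_x = comparison$only_x, only_y = comparison$only_y,
           shared_same_direction = comparison$shared_same_direction,
           shared_reversed_direction = comparison$shared_reversed_direction),
      file.path(output_dir, "comparison.json"),
      auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }

  manifest_path <- file.path(output_dir, "manifest.json")
  jsonlite::write_json(
    list(package = "rbmgrn",
         version = as.character(utils::packageVersion("rbmgrn")),
         r_version = R.version.string,
         seed = seed, theta = theta,
         config = config[c("learning_rate", "max_epochs", "error_tol",
                           "weight_diff_break", "backward_uses_transpose")],
         conditions = names(inputs),
         n_genes = purrr::map_int(raw, nrow),
         formats = formats, thetas = thetas),
    manifest_path, auto_unbox = TRUE, digits = NA)

  invisible(list(networks = networks, candidates = candidates,
                 edge_curves = edge_curves, comparison = comparison,
                 manifest = manifest_path))
}
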