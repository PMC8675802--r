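table4_candidates <- function() strength_matrix_candidates(fixture_tables()$table4)

test_that("the theta filter keeps exactly the worked example's pairs at 0.004", {
  kept <- filter_interactions(table4_candidates(), 0.004)
  expect_setequal(paste(kept$gene_a, kept$gene_b, sep = "-"),
                  c("Gene1-Gene3", "Gene2-Gene3", "Gene3-Gene4"))
  all_kept <- filter_interactions(table4_candidates(), 1.0)
  expect_equal(nrow(all_kept), 6L)
  expect_error(filter_interactions(table4_candidates(), 0), "positive")
})

test_that("the filter drops unconverged or strength-less pairs and is monotone", {
  cand <- random_candidates(40, seed = 7)
  cand$strength_a[1] <- NA_real_
  kept <- filter_interactions(cand, 0.05)
  expect_true(all(kept$converged))
  expect_false(any(is.na(kept$strength_a)))

  thetas <- c(0.002, 0.01, 0.05, 0.2, 1)
  for (i in seq_len(length(thetas) - 1)) {
    k1 <- filter_interactions(cand, thetas[i])
    k2 <- filter_interactions(cand, thetas[i + 1])
    expect_true(all(paste(k1$gene_a, k1$gene_b) %in% paste(k2$gene_a, k2$gene_b)))
  }
  # idempotence: filtering an already filtered set changes nothing
  expect_equal(filter_interactions(kept, 0.05), kept)
})

test_that("edge counts over a threshold sweep are non-decreasing", {
  curve <- edges_vs_threshold(table4_candidates(), c(0.001, 0.004, 0.02))
  expect_equal(curve$edge_count[2], 3L)
  expect_lte(curve$edge_count[1], 3L)
  expect_gte(curve$edge_count[3], 3L)
  expect_true(all(diff(curve$edge_count) >= 0))

  empty <- edges_vs_threshold(table4_candidates()[0, ], c(0.01, 0.02))
  expect_equal(empty$edge_count, c(0L, 0L))
  expect_error(edges_vs_threshold(table4_candidates(), c(0.02, 0.01)), "ascending")

  for (seed in 1:5) {
    curve <- edges_vs_threshold(random_candidates(30, seed), seq(0.01, 0.3, by = 0.02))
    expect_true(all(diff(curve$edge_count) >= 0))
  }
})

table5_expr <- function() {
  as_expr_tbl(fixture_tables()$table5)
}

test_that("networks orient accepted pairs on raw expression and keep the regulator's strength", {
  cand <- tibble::tibble(gene_a = "Gene1", gene_b = "Gene3",
                         strength_a = 0.772, strength_b = 0.77, converged = TRUE)
  net <- build_network(cand, table5_expr(), "demo", theta = 0.004)
  expect_equal(nrow(net$edges), 1L)
  expect_equal(net$edges$regulator, "Gene3")
  expect_equal(net$edges$target, "Gene1")
  expect_equal(net$edges$strength, 0.77) # Gene3's side of the pair

  empty <- build_network(cand[0, ], table5_expr(), "empty")
  expect_equal(nrow(empty$edges), 0L)
  expect_equal(empty$nodes, c("Gene1", "Gene3"))

  expect_error(build_network(
    tibble::tibble(gene_a = "GeneX", gene_b = "Gene3",
                   strength_a = 0.7, strength_b = 0.7, converged = TRUE),
    table5_expr(), "bad"), "GeneX")
})

test_that("edge count equals candidate count, one edge per unordered pair", {
  x <- toy_expr()
  cand <- tibble::tibble(gene_a = c("G1", "G1", "G2"), gene_b = c("G2", "G3", "G4"),
                         strength_a = c(0.7, 0.6, 0.5), strength_b = c(0.7, 0.6, 0.5),
                         converged = TRUE)
  net <- build_network(cand, x, "toy", 0.01)
  expect_equal(nrow(net$edges), nrow(cand))
  keys <- paste(pmin(net$edges$regulator, net$edges$target),
                pmax(net$edges$regulator, net$edges$target))
  expect_false(any(duplicated(keys)))
  expect_true(all(net$edges$strength >= 0 & net$edges$strength <= 1))
  expect_false(any(net$edges$regulator == net$edges$target))
})

make_net <- function(edges, nodes, label = "n") {
  structure(list(nodes = nodes,
                 edges = dplyr::mutate(edges, score_forward = 1,
                                       score_backward = 0, tie = FALSE),
                 condition_label = label, theta = 0.006), class = "grn")
}

test_that("network comparison partitions the pair union into four classes", {
  e1 <- tibble::tibble(regulator = c("A", "B"), target = c("B", "C"),
                       strength = c(0.7, 0.6))
  net1 <- make_net(e1, c("A", "B", "C", "D"))
  cmp_same <- compare_networks(net1, net1)
  expect_equal(cmp_same$counts$shared_same_direction, 2L)
  expect_equal(cmp_same$counts$only_x + cmp_same$counts$only_y +
               cmp_same$counts$shared_reversed_direction, 0L)

  e2 <- tibble::tibble(regulator = c("B", "C"), target = c("A", "D"),
                       strength = c(0.5, 0.4))
  cmp <- compare_networks(net1, make_net(e2, c("A", "B", "C", "D"), "m"))
  expect_equal(cmp$counts$shared_reversed_direction, 1L) # A->B vs B->A
  expect_equal(cmp$counts$only_x, 1L)                    # B->C
  expect_equal(cmp$counts$only_y, 1L)                    # C->D
  expect_equal(with(cmp$counts, only_x + only_y + shared_same_direction +
                    shared_reversed_direction), cmp$counts$pair_union)
  expect_equal(nrow(tidy(cmp)), cmp$counts$pair_union)
})

test_that("exports round trip through TSV and write graph formats", {
  cand <- filter_interactions(table4_candidates(), 0.004)
  t1 <- fixture_tables()$table1
  net <- build_network(cand, as_expr_tbl(t1[1:4, ]), "worked", 0.004)
  expect_equal(nrow(net$edges), 3L)

  tsv <- withr::local_tempfile(fileext = ".tsv")
  export_network(net, tsv, "tsv")
  back <- read_network_tsv(tsv)
  expect_equal(back$edges, net$edges[, c("regulator", "target", "strength", "tie")])
  expect_equal(back$theta, 0.004)
  expect_equal(back$condition_label, "worked")

  empty <- build_network(cand[0, ], as_expr_tbl(t1), "none")
  export_network(empty, tsv, "tsv")
  expect_equal(length(readLines(tsv)), 1L) # header only

  gml <- withr::local_tempfile(fileext = ".graphml")
  export_network(net, gml, "graphml")
  g <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::ecount(g), 3)
  expect_equal(sort(igraph::E(g)$strength), sort(net$edges$strength))

  dot <- withr::local_tempfile(fileext = ".dot")
  export_network(net, dot, "dot")
  expect_true(any(grepl("->", readLines(dot))))
  expect_error(export_network(net, tsv, "json"), "should be one of")
})

test_that("autoplot produces ggplot objects for curves and networks", {
  curve <- edges_vs_threshold(table4_candidates(), c(0.004, 0.008))
  expect_s3_class(autoplot(curve), "ggplot")
  cand <- filter_interactions(table4_candidates(), 0.004)
  net <- build_network(cand, as_expr_tbl(fixture_tables()$table1[1:4, ]), "w", 0.004)
  expect_s3_class(autoplot(net), "ggplot")
  expect_s3_class(glance(net), "tbl_df")
  expect_equal(glance(net)$n_edges, 3L)
})
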