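# Shared in-code fixtures for the suite; everything is built at test time.

# A small labelled expression table: 4 genes x 6 samples, two phenotype groups.
toy_expr <- function(seed = 42L) {
  withr::with_seed(seed, {
    m <- matrix(rnorm(24, mean = 6, sd = 1), 4, 6,
                dimnames = list(paste0("G", 1:4), paste0("S", 1:6)))
    as_expr_tbl(m, phenotype = setNames(rep(c("normal", "diseased"), each = 3),
                                        colnames(m)))
  })
}

# Exhaustive two-sided permutation p-value of the rank-sum statistic:
# enumerates every assignment of group-a labels to the pooled values.
permutation_ranksum_p <- function(a, b) {
  pooled <- c(a, b)
  n_a <- length(a)
  r <- rank(pooled)
  mu <- n_a * (length(pooled) + 1) / 2
  obs <- abs(sum(r[seq_len(n_a)]) - mu)
  picks <- combn(length(pooled), n_a)
  stats <- apply(picks, 2L, function(idx) abs(sum(r[idx]) - mu))
  mean(stats >= obs - 1e-9)
}

# A minimal GDS SOFT file written to `path`; `null_cell` injects a bad value.
write_soft_fixture <- function(path, null_cell = FALSE) {
  v <- c("1.2", "2.5", "0.7", "3.3")
  if (null_cell) v[2] <- "null"
  lines <- c(
    "^DATASET = GDS_TEST",
    "!dataset_title = tiny fixture",
    "^SUBSET = GDS_TEST_1",
    "!subset_description = normal",
    "!subset_sample_id = GSM1,GSM2",
    "^SUBSET = GDS_TEST_2",
    "!subset_description = diseased",
    "!subset_sample_id = GSM3,GSM4",
    "#ID_REF = probe id",
    paste(c("ID_REF", "IDENTIFIER", "GSM1", "GSM2", "GSM3", "GSM4"), collapse = "\t"),
    paste(c("p1", "TP53", v), collapse = "\t"),
    paste(c("p2", "BRCA1", "4.1", "4.4", "4.0", "4.9"), collapse = "\t"),
    paste(c("p3", "", "2.2", "2.0", "2.8", "2.4"), collapse = "\t")
  )
  writeLines(lines, path)
  path
}

# Replays a recorded training trajectory by composing the exported step
# operations, independent of train_pair's internal loop.
replay_pair <- function(g_a, g_b, fit) {
  cfg <- fit$config
  n <- length(g_a)
  st <- withr::with_seed(cfg$seed, init_pair(n))
  w1 <- st$w1; w2 <- st$w2; bias <- st$bias
  out <- NULL
  for (epoch in seq_len(fit$epochs_run)) {
    thr <- fit$history[[epoch]]$thresholds
    fa <- forward_pass(g_a, w1, bias, thr)
    fb <- forward_pass(g_b, w2, bias, thr)
    src_a <- if (epoch == 1L) fa$act else fb$act
    src_b <- if (epoch == 1L) fb$act else fa$act
    ba <- backward_pass(src_a, w1, bias, cfg$backward_uses_transpose)
    bb <- backward_pass(src_b, w2, bias, cfg$backward_uses_transpose)
    err_a <- reconstruction_error(g_a, ba$recon_act)
    err_b <- reconstruction_error(g_b, bb$recon_act)
    w1 <- update_weights(w1, associations(g_a, fa$act),
                         associations(ba$recon_act, ba$hidden_act),
                         cfg$learning_rate, n)
    w2 <- update_weights(w2, associations(g_b, fb$act),
                         associations(bb$recon_act, bb$hidden_act),
                         cfg$learning_rate, n)
    out <- list(strengths = matched_strengths(fa$act, fb$act, fa$state, fb$state),
                error_a = err_a, error_b = err_b, w1 = w1, w2 = w2)
  }
  out
}

random_candidates <- function(n, seed) {
  withr::with_seed(seed, tibble::tibble(
    gene_a = sprintf("a%02d", seq_len(n)),
    gene_b = sprintf("b%02d", seq_len(n)),
    strength_a = runif(n, 0.4, 0.8),
    strength_b = runif(n, 0.4, 0.8),
    converged = runif(n) < 0.8
  ))
}
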