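#' Configuration for paired-RBM training
#'
#' Bundles the training hyperparameters. The reconstruction-error floor
#' (`error_tol = 0.01`) and the strength-divergence break (`weight_diff_break
#' = 0.01`) come with the method; the learning rate, epoch cap and bias
#' handling are free choices and configurable.
#'
#' @param learning_rate Positive step size for the contrastive update.
#' @param max_epochs Epoch cap per pair.
#' @param error_tol A pair counts as converged once BOTH genes' summed squared
#'   reconstruction errors fall to this value or below.
#' @param weight_diff_break Training stops early once the two interaction
#'   strengths differ by more than this (such a pair cannot survive any
#'   acceptance threshold in the conventional range).
#' @param seed Optional integer seed making a single [train_pair()] call
#'   reproducible; [train_all_pairs()] derives one seed per pair instead.
#' @param backward_uses_transpose Passed to [backward_pass()].
#' @return A list of class `rbm_config`.
#' @export
rbm_config <- function(learning_rate = 0.1, max_epochs = 1000, error_tol = 0.01,
                       weight_diff_break = 0.01, seed = NULL,
                       backward_uses_transpose = TRUE) {
  stopifnot(learning_rate >= 0, max_epochs >= 1, error_tol > 0, weight_diff_break > 0)
  structure(list(learning_rate = learning_rate, max_epochs = as.integer(max_epochs),
                 error_tol = error_tol, weight_diff_break = weight_diff_break,
                 seed = if (!is.null(seed)) as.integer(seed),
                 backward_uses_transpose = isTRUE(backward_uses_transpose)),
            class = "rbm_config")
}

#' Train one bridged RBM pair on two gene vectors
#'
#' Runs the paired training loop on two normalized expression vectors. Each
#' epoch: one fresh random threshold vector is drawn and SHARED by both RBMs;
#' both genes are propagated forward; each gene is reconstructed from its own
#' forward hidden activation at epoch 1 and from its PARTNER's from epoch 2
#' onward (the bridge); squared reconstruction errors and the forward/backward
#' associations are computed; both weight matrices receive the contrastive
#' update. Training ends when both errors reach `error_tol`, when the two
#' interaction strengths diverge past `weight_diff_break`, or at `max_epochs`.
#' The reported strengths are the matched-active-unit means of the final
#' epoch's activations.
#'
#' @param g_a,g_b Normalized expression vectors (values in `[0, 1]`, length
#'   `n >= 2`); run [maxmin_normalize()] first.
#' @param config An [rbm_config()].
#' @param gene_a,gene_b Ids recorded in the result.
#' @param keep_history Record per-epoch thresholds, errors and strengths
#'   (used by replay-style checks; off by default).
#' @return An object of class `rbm_pair_fit`: gene ids, `strength_a`,
#'   `strength_b` (NA when no hidden unit was active in both RBMs),
#'   `error_a`, `error_b`, `epochs_run`, `converged`, `matched_units`, the
#'   final `w1`, `w2`, `bias`, and optionally `history`.
#' @examples
#' g <- c(0.64, 0, 0.44, 0.57, 1, 0.2)
#' train_pair(g, rev(g), rbm_config(max_epochs = 50, seed = 1))
#' @export
train_pair <- function(g_a, g_b, config = rbm_config(), gene_a = "gene_a",
                       gene_b = "gene_b", keep_history = FALSE) {
  g_a <- check_numeric_vector(g_a, "g_a")
  g_b <- check_numeric_vector(g_b, "g_b")
  check_same_length(g_a, g_b, "g_a", "g_b")
  if (length(g_a) < 2L) abort("Need at least two samples per gene.")
  if (min(g_a, g_b) < 0 || max(g_a, g_b) > 1) {
    abort("Expression values must lie in [0, 1]; apply maxmin_normalize() first.")
  }
  run <- function() train_pair_loop(g_a, g_b, config, gene_a, gene_b, keep_history)
  if (!is.null(config$seed)) withr::with_seed(config$seed, run()) else run()
}

train_pair_loop <- function(g_a, g_b, config, gene_a, gene_b, keep_history) {
  n <- length(g_a)
  st <- init_pair(n)
  w1 <- st$w1; w2 <- st$w2; bias <- st$bias
  transpose <- config$backward_uses_transpose
  converged <- FALSE
  err_a <- err_b <- Inf
  strengths <- list(strength_a = NA_real_, strength_b = NA_real_, matched_units = 0L)
  history <- if (keep_history) list() else NULL
  epoch <- 0L

  while (epoch < config$max_epochs) {
    epoch <- epoch + 1L
    thresholds <- runif(n)

    fa <- forward_pass(g_a, w1, bias, thresholds)
    fb <- forward_pass(g_b, w2, bias, thresholds)

    src_a <- if (epoch == 1L) fa$act else fb$act
    src_b <- if (epoch == 1L) fb$act else fa$act
    ba <- backward_pass(src_a, w1, bias, use_transpose = transpose)
    bb <- backward_pass(src_b, w2, bias, use_transpose = transpose)

    err_a <- reconstruction_error(g_a, ba$recon_act)
    err_b <- reconstruction_error(g_b, bb$recon_act)

    w1 <- update_weights(w1, associations(g_a, fa$act),
                         associations(ba$recon_act, ba$hidden_act),
                         config$learning_rate, n)
    w2 <- update_weights(w2, associations(g_b, fb$act),
                         associations(bb$recon_act, bb$hidden_act),
                         config$learning_rate, n)

    strengths <- matched_strengths(fa$act, fb$act, fa$state, fb$state)
    if (keep_history) {
      history[[epoch]] <- list(thresholds = thresholds, error_a = err_a,
                               error_b = err_b, strengths = strengths)
    }

    if (err_a <= config$error_tol && err_b <= config$error_tol) {
      converged <- TRUE
      break
    }
    diff <- abs(strengths$strength_a - strengths$strength_b)
    if (!is.na(diff) && diff > config$weight_diff_break) break
  }

  structure(list(gene_a = gene_a, gene_b = gene_b,
                 strength_a = strengths$strength_a,
                 strength_b = strengths$strength_b,
                 error_a = err_a, error_b = err_b,
                 epochs_run = epoch, converged = converged,
                 matched_units = strengths$matched_units,
                 w1 = w1, w2 = w2, bias = bias,
                 config = config, history = history),
            class = "rbm_pair_fit")
}

#' @export
print.rbm_pair_fit <- function(x, ...) {
  cat(sprintf("<rbm_pair_fit> %s -- %s\n", x$gene_a, x$gene_b))
  cat(sprintf("  strengths: %.4f / %.4f over %d matched unit(s)\n",
              x$strength_a, x$strength_b, x$matched_units))
  cat(sprintf("  errors: %.4g / %.4g after %d epoch(s); converged: %s\n",
              x$error_a, x$error_b, x$epochs_run, x$converged))
  invisible(x)
}

#' @export
tidy.rbm_pair_fit <- function(x, ...) {
  tibble::tibble(gene_a = x$gene_a, gene_b = x$gene_b,
                 strength_a = x$strength_a, strength_b = x$strength_b,
                 error_a = x$error_a, error_b = x$error_b,
                 epochs_run = x$epochs_run, converged = x$converged,
                 matched_units = x$matched_units)
}

#' @export
glance.rbm_pair_fit <- function(x, ...) {
  tibble::tibble(epochs_run = x$epochs_run, converged = x$converged,
                 strength_gap = abs(x$strength_a - x$strength_b),
                 max_error = max(x$error_a, x$error_b))
}

#' Train a bridged RBM pair for every unordered gene pair
#'
#' Applies [train_pair()] to each of the `choose(m, 2)` unordered pairs of a
#' normalized expression table, visiting pairs in lexicographic gene-id order.
#' Each pair trains under its own seed derived via [pair_seed()] from the
#' global `seed` and the two ids, so the candidate table is reproducible and
#' independent of iteration order.
#'
#' @param x A normalized `expr_tbl` (all values in `[0, 1]`).
#' @param config An [rbm_config()]; its `seed` field is ignored here.
#' @param seed Global integer seed.
#' @return A tibble of class `rbm_candidates` with one row per pair: `gene_a <
#'   gene_b`, both strengths, both errors, `epochs_run`, `converged`,
#'   `matched_units`.
#' @export
train_all_pairs <- function(x, config = rbm_config(), seed = 1L) {
  ids <- sort(expr_genes(x))
  if (length(ids) < 2L) abort("Need at least two genes.")
  m <- expr_values(x)
  pairs <- combn(ids, 2L)
  rows <- purrr::map(seq_len(ncol(pairs)), function(k) {
    a <- pairs[1L, k]; b <- pairs[2L, k]
    cfg <- config
    cfg$seed <- pair_seed(seed, a, b)
    tidy(train_pair(m[a, ], m[b, ], cfg, gene_a = a, gene_b = b))
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "seed") <- as.integer(seed)
  attr(out, "config") <- config
  class(out) <- c("rbm_candidates", class(out))
  out
}

#' @export
glance.rbm_candidates <- function(x, ...) {
  tibble::tibble(n_pairs = nrow(x), n_converged = sum(x$converged),
                 mean_epochs = mean(x$epochs_run),
                 mean_strength_gap = mean(abs(x$strength_a - x$strength_b), na.rm = TRUE))
}
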