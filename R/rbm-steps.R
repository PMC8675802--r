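#' RBM energy
#'
#' The energy of a visible/hidden configuration of a binary restricted
#' Boltzmann machine: `-v' W h - b.v - c.h`, with `w[j, i]` the weight between
#' visible unit `j` and hidden unit `i`. Diagnostic only — the pair-training
#' procedure never evaluates it.
#'
#' @param v,h Binary (0/1) visible and hidden state vectors.
#' @param w Weight matrix, visible units in rows, hidden units in columns.
#' @param b_vis,c_hid Visible and hidden bias vectors.
#' @return A single number.
#' @export
rbm_energy <- function(v, h, w, b_vis, c_hid) {
  v <- check_numeric_vector(v, "v"); h <- check_numeric_vector(h, "h")
  if (!is.matrix(w) || nrow(w) != length(v) || ncol(w) != length(h)) {
    abort("`w` must be a length(v) x length(h) matrix.")
  }
  check_same_length(v, b_vis, "v", "b_vis")
  check_same_length(h, c_hid, "h", "c_hid")
  -drop(v %*% w %*% h) - sum(b_vis * v) - sum(c_hid * h)
}

#' Initialize a bridged RBM pair
#'
#' Both weight matrices are the SAME draw: entries of `w1` are sampled
#' uniformly from `[-1/n, +1/n]` and `w2` starts as a copy, which is what
#' makes training two identical gene vectors produce exactly equal interaction
#' strengths. The single shared bias vector starts at zero and is never
#' updated. The hidden layer has the same width `n` as the visible layer (one
#' unit per sample).
#'
#' @param n_units Number of visible/hidden units (= number of samples).
#' @param seed Integer seed; equal seeds give bitwise-identical states.
#' @return A list with `w1`, `w2` (n x n), `bias` (length n), `epoch = 0`.
#' @export
init_pair <- function(n_units, seed = NULL) {
  if (!is.numeric(n_units) || n_units < 1) abort("`n_units` must be a positive integer.")
  n_units <- as.integer(n_units)
  draw <- function() matrix(runif(n_units^2, -1 / n_units, 1 / n_units), n_units, n_units)
  w1 <- if (is.null(seed)) draw() else withr::with_seed(as.integer(seed), draw())
  list(w1 = w1, w2 = w1, bias = numeric(n_units), epoch = 0L)
}

#' One forward propagation step
#'
#' Hidden pre-activations are `bias + g %*% w`; activations are their logistic
#' transform; the binary hidden state switches a unit on where its activation
#' exceeds the caller-supplied random threshold. The SAME threshold vector must
#' be passed for both genes of a pair within an epoch.
#'
#' @param g Visible input vector (normalized gene expression, length n).
#' @param w n x n weight matrix (visible rows, hidden columns).
#' @param bias Bias vector, length n.
#' @param thresholds Activation thresholds in (0, 1), length n.
#' @return A list with `pre_act`, `act` and logical `state`.
#' @export
forward_pass <- function(g, w, bias, thresholds) {
  g <- check_numeric_vector(g, "g")
  if (!is.matrix(w) || nrow(w) != length(g) || ncol(w) != length(g)) {
    abort("`w` must be an n x n matrix matching length(g).")
  }
  check_same_length(g, bias, "g", "bias")
  check_same_length(g, thresholds, "g", "thresholds")
  pre <- drop(bias + g %*% w)
  act <- plogis(pre)
  list(pre_act = pre, act = act, state = act > thresholds)
}

#' One backward (reconstruction) step
#'
#' Reconstructs the visible layer from a hidden activation vector and
#' re-activates the hidden layer from that reconstruction. From the second
#' epoch of pair training onward, `h_source` is the PARTNER gene's forward
#' hidden activation — the bridge that makes each RBM rebuild its own gene
#' from the other gene's features.
#'
#' With `use_transpose = TRUE` (default) the reconstruction multiplies by
#' `t(w)`, the standard RBM contract of reusing one weight matrix in both
#' directions; `FALSE` keeps the same orientation in both passes, which only
#' coincides with the default when `w` is symmetric.
#'
#' @param h_source Hidden activation vector driving the reconstruction.
#' @inheritParams forward_pass
#' @param use_transpose Reconstruct through `t(w)` (default) or through `w`.
#' @return A list with `recon_act` (visible reconstruction) and `hidden_act`.
#' @export
backward_pass <- function(h_source, w, bias, use_transpose = TRUE) {
  h_source <- check_numeric_vector(h_source, "h_source")
  if (!is.matrix(w) || nrow(w) != length(h_source) || ncol(w) != length(h_source)) {
    abort("`w` must be an n x n matrix matching length(h_source).")
  }
  check_same_length(h_source, bias, "h_source", "bias")
  wm <- if (use_transpose) t(w) else w
  recon <- plogis(drop(bias + h_source %*% wm))
  hidden <- plogis(drop(bias + recon %*% w))
  list(recon_act = recon, hidden_act = hidden)
}

#' Visible-hidden association matrix
#'
#' Outer product `result[j, i] = v[j] * h_act[i]`. The difference between the
#' forward association (raw gene times forward hidden activation) and the
#' backward association (reconstructed visible times backward hidden
#' activation) drives the weight update, as in one step of contrastive
#' divergence.
#'
#' @param v Visible vector.
#' @param h_act Hidden activation vector.
#' @return An n x n matrix of rank at most 1.
#' @export
associations <- function(v, h_act) {
  v <- check_numeric_vector(v, "v"); h_act <- check_numeric_vector(h_act, "h_act")
  check_same_length(v, h_act, "v", "h_act")
  outer(v, h_act)
}

#' Sum-of-squares reconstruction error
#'
#' @param original,reconstructed Equal-length numeric vectors.
#' @return `sum((original - reconstructed)^2)`.
#' @export
reconstruction_error <- function(original, reconstructed) {
  original <- check_numeric_vector(original, "original")
  reconstructed <- check_numeric_vector(reconstructed, "reconstructed")
  check_same_length(original, reconstructed, "original", "reconstructed")
  sum((original - reconstructed)^2)
}

#' Contrastive weight update
#'
#' Returns `w + learning_rate * (f_assoc - b_assoc) / n_units`; the input is
#' not modified.
#'
#' @param w Current weight matrix.
#' @param f_assoc,b_assoc Forward and backward association matrices.
#' @param learning_rate Positive step size.
#' @param n_units Number of input units (the divisor).
#' @return The updated weight matrix.
#' @export
update_weights <- function(w, f_assoc, b_assoc, learning_rate, n_units) {
  if (!all(dim(w) == dim(f_assoc)) || !all(dim(w) == dim(b_assoc))) {
    abort("`w`, `f_assoc` and `b_assoc` must share dimensions.")
  }
  w + learning_rate * (f_assoc - b_assoc) / n_units
}

#' Interaction strengths over matched active hidden units
#'
#' The matched set M holds the hidden positions whose state is active in BOTH
#' RBMs at the final epoch. Each gene's interaction strength is the mean of its
#' own activation probabilities over M; with no matched unit both strengths
#' are undefined (`NA`).
#'
#' @param act_a,act_b Hidden activation vectors of the two genes.
#' @param state_a,state_b Logical hidden state vectors of the two genes.
#' @return A list with `strength_a`, `strength_b` and `matched_units`.
#' @export
matched_strengths <- function(act_a, act_b, state_a, state_b) {
  check_same_length(act_a, act_b, "act_a", "act_b")
  check_same_length(act_a, state_a, "act_a", "state_a")
  check_same_length(act_a, state_b, "act_a", "state_b")
  m <- state_a & state_b
  if (!any(m)) {
    return(list(strength_a = NA_real_, strength_b = NA_real_, matched_units = 0L))
  }
  list(strength_a = mean(act_a[m]), strength_b = mean(act_b[m]),
       matched_units = sum(m))
}
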