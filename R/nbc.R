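#' Gaussian parameters of one gene's expression
#'
#' Mean and POPULATION standard deviation (divisor `n`, not `n - 1`) of a raw
#' expression vector; these are the class-conditional parameters the direction
#' classifier fits to each candidate regulator.
#'
#' @param values Numeric vector, length >= 2, not all equal.
#' @return A list of class `gaussian_params` with `mu` and `sigma`.
#' @export
gaussian_params <- function(values) {
  values <- check_numeric_vector(values, "values")
  if (length(values) < 2L) abort("Need at least two values.")
  mu <- mean(values)
  sigma <- sqrt(mean((values - mu)^2))
  if (sigma == 0) abort("All values are equal; the Gaussian is degenerate.")
  structure(list(mu = mu, sigma = sigma), class = "gaussian_params")
}

#' Normal density
#'
#' Evaluates the Gaussian density `g(x, mu, sigma)` used by the naive-Bayes
#' direction rule.
#'
#' @param x Point(s) of evaluation.
#' @param params A [gaussian_params()] object.
#' @return Density value(s).
#' @export
gaussian_density <- function(x, params) {
  stopifnot(inherits(params, "gaussian_params"))
  dnorm(x, mean = params$mu, sd = params$sigma)
}

#' Score one regulation direction
#'
#' How well does the candidate regulator's fitted Gaussian explain the
#' candidate target's typical expression? The score is the density of the
#' target's MEAN expression under `gaussian_params(candidate_regulator)`. The
#' mean is the summary evaluated because the classifier needs a single
#' representative value per gene; it makes the decision a deterministic
#' function of the two (mu, sigma) pairs.
#'
#' @param candidate_target,candidate_regulator Raw expression vectors.
#' @return A non-negative number; larger means the regulator's distribution
#'   explains the target better.
#' @export
regulation_score <- function(candidate_target, candidate_regulator) {
  gaussian_density(mean(check_numeric_vector(candidate_target, "candidate_target")),
                   gaussian_params(candidate_regulator))
}

#' Decide which gene of a pair regulates the other
#'
#' Computes both directed scores and names as regulator the gene whose
#' distribution better explains the partner's mean expression: if
#' `regulation_score(a under b) > regulation_score(b under a)`, then `b`
#' regulates `a`. Exact ties are flagged and resolved toward the
#' lexicographically smaller id so downstream network assembly stays
#' deterministic. The decision is invariant to argument order.
#'
#' @param gene_a,gene_b Raw expression vectors.
#' @param id_a,id_b Gene identifiers.
#' @return A one-row tibble: `regulator`, `target`, `score_forward` (winning
#'   direction), `score_backward`, `tie`.
#' @examples
#' t5 <- fixture_tables()$table5
#' decide_direction(t5["Gene1", ], t5["Gene3", ], "Gene1", "Gene3")
#' @export
decide_direction <- function(gene_a, gene_b, id_a = "gene_a", id_b = "gene_b") {
  s_ab <- regulation_score(gene_a, gene_b) # b explains a => b -> a
  s_ba <- regulation_score(gene_b, gene_a) # a explains b => a -> b
  if (s_ab == s_ba) {
    ids <- sort(c(id_a, id_b))
    return(tibble::tibble(regulator = ids[1L], target = ids[2L],
                          score_forward = s_ab, score_backward = s_ba, tie = TRUE))
  }
  if (s_ab > s_ba) {
    tibble::tibble(regulator = id_b, target = id_a,
                   score_forward = s_ab, score_backward = s_ba, tie = FALSE)
  } else {
    tibble::tibble(regulator = id_a, target = id_b,
                   score_forward = s_ba, score_backward = s_ab, tie = FALSE)
  }
}
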