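# 32-bit FNV-1a over a string, done in doubles to avoid integer overflow.
# Used only to derive reproducible per-pair RNG seeds.
fnv1a32 <- function(x) {
  bytes <- as.integer(charToRaw(x))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b) + (h %/% 2^31) * 2^31
    lo <- h %% 65536
    hi <- h %/% 65536
    h <- (lo * 16777619 + ((hi * 16777619) %% 65536) * 65536) %% 2^32
  }
  h
}

#' Derive a reproducible seed for one gene pair
#'
#' Seeds for per-pair RBM training are a deterministic function of the global
#' seed and the two gene ids, with the ids sorted first, so whole-matrix runs
#' give identical results regardless of the order pairs are visited in.
#'
#' @param seed Integer global seed.
#' @param id_a,id_b Gene identifiers (order does not matter).
#' @return An integer in `[0, 2^31)`.
#' @export
pair_seed <- function(seed, id_a, id_b) {
  ids <- sort(c(as.character(id_a), as.character(id_b)))
  h <- fnv1a32(paste(ids, collapse = "\r"))
  as.integer((as.numeric(seed) %% 2^31 * 69069 + h) %% 2147483647)
}

check_numeric_vector <- function(x, arg) {
  if (!is.numeric(x) || anyNA(x)) {
    abort(sprintf("`%s` must be a numeric vector with no missing values.", arg))
  }
  as.numeric(x)
}

check_same_length <- function(a, b, arg_a, arg_b) {
  if (length(a) != length(b)) {
    abort(sprintf("`%s` (length %d) and `%s` (length %d) must have equal length.",
                  arg_a, length(a), arg_b, length(b)))
  }
  invisible(NULL)
}
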