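#' Boltzmann constant in molar energy units
#'
#' `k_B` = 0.008314462618 kJ mol^-1 K^-1, the constant used throughout the
#' package to convert between energies (kJ/mol) and thermal units (k_B T).
#'
#' @format A length-one numeric.
#' @export
KB_KJ_MOL_K <- 0.008314462618

# 1/(k_B T) in mol/kJ
beta_of <- function(temperature) {
  stopifnot(is.numeric(temperature), length(temperature) == 1L, temperature > 0)
  1 / (KB_KJ_MOL_K * temperature)
}

#' Derive a child seed from a master seed
#'
#' Deterministic splitting rule used by every generator that runs several
#' independent streams (umbrella windows, lambda states, bootstrap
#' replicates): `child = (seed + 1000003 * index) mod (2^31 - 1)`, kept
#' strictly positive. The same `(seed, index)` pair always yields the same
#' stream.
#'
#' @param seed master seed (integer).
#' @param index stream index, 1-based.
#' @return An integer seed usable with [set.seed()].
#' @export
split_seed <- function(seed, index) {
  stopifnot(length(seed) == 1L, length(index) == 1L, is.finite(seed), index >= 0)
  m <- 2147483647
  s <- (as.numeric(seed) %% m + 1000003 * (as.numeric(index) %% m)) %% m
  as.integer(s + 1)
}

# numerically stable log(sum(exp(x)))
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# row-wise logsumexp of a matrix plus per-column offsets: log sum_k exp(A[k, ] + b[k])
logsumexp_cols <- function(A, b = NULL) {
  if (!is.null(b)) A <- A + b
  m <- apply(A, 2L, max)
  m + log(colSums(exp(sweep(A, 2L, m))))
}
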