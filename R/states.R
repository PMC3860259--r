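#' Convert a gene activity profile to its state index
#'
#' States of an n-gene network are numbered 0..2^n-1 with gene 1 as the most
#' significant bit, so the all-zero profile is state 0 and the all-one profile
#' is state 2^n - 1.
#'
#' @param bits integer (0/1) vector, one entry per gene; gene 1 first.
#' @return a single integer in `[0, 2^length(bits))`.
#' @seealso [index_to_state()]
#' @export
#' @examples
#' state_to_index(c(1, 0, 0))  # 4
state_to_index <- function(bits) {
  if (!is.numeric(bits) || length(bits) < 1L || any(is.na(bits)) ||
      !all(bits %in% c(0, 1))) {
    stop("`bits` must be a non-empty 0/1 vector")
  }
  n <- length(bits)
  as.integer(sum(bits * 2^((n - 1):0)))
}

#' Convert a state index back to a gene activity profile
#'
#' @param index integer in `[0, 2^n)`.
#' @param n number of genes.
#' @return integer 0/1 vector of length `n`, gene 1 first (most significant).
#' @export
index_to_state <- function(index, n) {
  if (index < 0 || index >= 2^n) stop("`index` out of range for n = ", n)
  bitwAnd(bitwShiftR(as.integer(index), (n - 1):0), 1L)
}

#' Enumerate all gene activity profiles of an n-gene network
#'
#' @param n number of genes (n <= 14 kept in scope; the state space is 2^n).
#' @return a `2^n x n` integer 0/1 matrix; row `i` is the profile of state
#'   `i - 1` under the gene-1-most-significant convention.
#' @export
all_states <- function(n) {
  N <- 2^n
  m <- matrix(0L, N, n)
  for (j in seq_len(n)) m[, j] <- bitwAnd(bitwShiftR(0:(N - 1), n - j), 1L)
  m
}

#' States matching a marker gene value
#'
#' Returns the 1-based row indices (into the `all_states(n)` ordering) of all
#' states in which `gene` takes `value`; the usual way to define the
#' undesirable set from a phenotype marker.
#'
#' @param n number of genes.
#' @param gene 1-based marker gene index.
#' @param value 0 or 1.
#' @return integer vector of 1-based state indices.
#' @export
marker_states <- function(n, gene, value) {
  stopifnot(gene >= 1, gene <= n, value %in% c(0, 1))
  bit <- bitwAnd(bitwShiftR(0:(2^n - 1), n - gene), 1L)
  which(bit == value)
}

#' Aggregate probability mass on a set of states
#'
#' @param pi a steady-state (or any probability) vector over states.
#' @param states integer vector of 1-based state indices.
#' @return the summed mass.
#' @export
state_mass <- function(pi, states) {
  if (length(states) == 0L) return(0)
  sum(pi[states])
}

# 1-based permutation sending each state to the state with `gene` toggled
flip_permutation <- function(n, gene) {
  stopifnot(gene >= 1, gene <= n)
  bitwXor(0:(2^n - 1), bitwShiftL(1L, n - gene)) + 1L
}

# popcount of 0..(2^n - 1), used for perturbation Hamming distances
bit_counts <- function(n) {
  v <- 0:(2^n - 1)
  out <- integer(length(v))
  for (j in 0:(n - 1)) out <- out + bitwAnd(bitwShiftR(v, j), 1L)
  out
}
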