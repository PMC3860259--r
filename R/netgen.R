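#' Generate a random Boolean network with perturbation
#'
#' Emulates sparse regulatory wiring: each gene's in-degree is uniform on
#' `1..K`, its regulators a uniform k-subset of all genes (self-loops allowed),
#' and its truth-table column is filled with i.i.d. Bernoulli bits whose bias
#' is drawn once per gene from a Beta distribution with the given mean and
#' standard deviation. With `bias_mean = 0.5, bias_sd = 0.01` the Beta shape
#' parameters are `alpha = beta = 1249.5`, so output columns are balanced.
#'
#' @param n gene count.
#' @param K maximum in-degree, `1 <= K <= n`.
#' @param p perturbation probability.
#' @param bias_mean,bias_sd mean and sd of the per-gene truth-table bias.
#' @param seed optional integer; when given the generator is reseeded so the
#'   same seed always yields the same network.
#' @return a [bnp()].
#' @export
generate_random_bnp <- function(n, K = 3, p = 0.01,
                                bias_mean = 0.5, bias_sd = 0.01, seed = NULL) {
  stopifnot(K >= 1, K <= n, bias_sd^2 < bias_mean * (1 - bias_mean))
  if (!is.null(seed)) set.seed(seed)
  # method-of-moments Beta parameters
  v <- bias_sd^2
  common <- bias_mean * (1 - bias_mean) / v - 1
  alpha <- bias_mean * common
  beta <- (1 - bias_mean) * common
  tables <- vector("list", n)
  for (i in seq_len(n)) {
    k <- sample.int(K, 1L)
    regs <- sort(sample.int(n, k))
    b <- stats::rbeta(1, alpha, beta)
    out <- stats::rbinom(2^k, 1L, b)
    tables[[i]] <- truth_table(i, regs, out)
  }
  bnp(tables, p)
}

#' Simulate time series of gene activity profiles from a BNp
#'
#' Each series starts from a uniformly random state; at every step a
#' perturbation vector `gamma ~ Bernoulli(p)^n` is drawn, and the next state is
#' `x XOR gamma` if any gene is perturbed, else the deterministic update
#' `f(x)`. The `M` observed transitions are split as evenly as possible across
#' `n_series` series (series of `t` transitions has `t + 1` rows).
#'
#' @param net a [bnp()].
#' @param M total number of observed state transitions, `M >= 1`.
#' @param n_series number of separate series to split `M` across.
#' @param seed optional integer reseed.
#' @param init `"uniform"` (default) or a fixed 0/1 profile used as the start
#'   of every series.
#' @return list of integer 0/1 matrices, one per series, rows = time points,
#'   columns = genes.
#' @export
generate_time_series <- function(net, M, n_series = 1L, seed = NULL,
                                 init = "uniform") {
  if (M < 1) stop("`M` must be >= 1")
  if (n_series < 1 || n_series > M) stop("`n_series` must be in 1..M")
  if (!is.null(seed)) set.seed(seed)
  n <- net$n
  img <- state_images(net)
  base <- M %/% n_series
  lens <- rep(base, n_series) + (seq_len(n_series) <= M %% n_series)
  S <- all_states(n)
  lapply(lens, function(tlen) {
    out <- matrix(0L, tlen + 1L, n)
    if (identical(init, "uniform")) {
      s <- sample.int(2^n, 1L)
    } else {
      s <- state_to_index(init) + 1L
    }
    out[1L, ] <- S[s, ]
    for (t in seq_len(tlen)) {
      gamma <- stats::runif(n) < net$p
      if (any(gamma)) {
        s <- bitwXor(s - 1L, state_to_index(as.integer(gamma))) + 1L
      } else {
        s <- img[s]
      }
      out[t + 1L, ] <- S[s, ]
    }
    out
  })
}

#' Stack the observed transitions of one or more series
#'
#' Consecutive rows within each series form one transition; series boundaries
#' never contribute a pair.
#'
#' @param series list of time-series matrices (as from
#'   [generate_time_series()]) or a single matrix.
#' @return list with matrices `from` and `to`, each `M x n`.
#' @export
transition_pairs <- function(series) {
  if (is.matrix(series)) series <- list(series)
  from <- do.call(rbind, lapply(series, function(m) m[-nrow(m), , drop = FALSE]))
  to <- do.call(rbind, lapply(series, function(m) m[-1L, , drop = FALSE]))
  list(from = from, to = to)
}
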