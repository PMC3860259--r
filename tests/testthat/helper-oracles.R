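# Independent oracles and tiny fixture networks used across the suite.

# identity network: each gene regulated by itself, x_i' = x_i
identity_net <- function(n, p = 0.01) {
  bnp(lapply(seq_len(n), function(i) truth_table(i, i, c(0L, 1L))), p)
}

# constant network: every gene's update is the constant `value`
constant_net <- function(n, value = 1L, p = 0.01) {
  bnp(lapply(seq_len(n), function(i) truth_table(i, 1L, c(value, value))), p)
}

# brute-force BNp transition matrix: enumerate all 2^n perturbation vectors
# and accumulate their probabilities (independent of build_tpm_bnp's algebra)
oracle_tpm <- function(net) {
  n <- net$n
  N <- 2^n
  p <- net$p
  S <- all_states(n)
  P <- matrix(0, N, N)
  for (s in seq_len(N)) {
    fx <- state_to_index(next_state_deterministic(net, S[s, ])) + 1L
    P[s, fx] <- P[s, fx] + (1 - p)^n
    for (g in seq_len(N - 1)) {            # non-zero perturbation vectors
      gamma <- index_to_state(g, n)
      dest <- state_to_index(as.integer(bitwXor(S[s, ], gamma))) + 1L
      P[s, dest] <- P[s, dest] + p^sum(gamma) * (1 - p)^(n - sum(gamma))
    }
  }
  P
}

# power-iteration steady state (oracle for the direct linear solve)
oracle_steady_power <- function(P, iters = 200000, tol = 1e-13) {
  v <- rep(1 / nrow(P), nrow(P))
  for (i in seq_len(iters)) {
    v2 <- as.numeric(crossprod(P, v))
    if (max(abs(v2 - v)) < tol) return(v2)
    v <- v2
  }
  v
}

# exhaustive MSSA oracle: enumerate all 2^N deterministic stationary policies
oracle_best_policy <- function(P, U, control_gene) {
  N <- nrow(P)
  base <- sum(steady_state(P)[U])
  best <- -Inf
  for (code in 0:(2^N - 1)) {
    pol <- bitwAnd(bitwShiftR(code, (N - 1):0), 1L)
    piv <- steady_state(controlled_tpm(P, pol, control_gene))
    best <- max(best, base - sum(piv[U]))
  }
  best
}

# brute-force minimum misclassification over all 2^(2^k) Boolean functions
oracle_min_error <- function(counts) {
  R <- length(counts$n0)
  best <- Inf
  for (code in 0:(2^R - 1)) {
    f <- bitwAnd(bitwShiftR(code, (R - 1):0), 1L)
    err <- sum(ifelse(f == 1, counts$n0, counts$n1))
    best <- min(best, err)
  }
  best
}

# noise-free full-coverage sample: every state paired with its deterministic
# successor, presented as 2-row series so no spurious transitions are added
full_coverage_series <- function(net) {
  S <- all_states(net$n)
  img <- state_images(net)
  lapply(seq_len(nrow(S)), function(s) rbind(S[s, ], S[img[s], ]))
}

# a small net whose functions genuinely depend on every listed regulator
xor_chain_net <- function(n, p = 0.01) {
  tables <- vector("list", n)
  tables[[1]] <- truth_table(1, n, c(0L, 1L))              # x1' = xn
  for (i in 2:n) {
    tables[[i]] <- truth_table(i, c(i - 1L, i), c(0L, 1L, 1L, 0L))  # XOR
  }
  bnp(tables, p)
}
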