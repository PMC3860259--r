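#' Construct a single-gene truth table
#'
#' A truth table records one gene's regulator set and its Boolean update rule
#' as an output column over all regulator input combinations. Row `r` (0-based)
#' of `outputs` is the function value when the regulator tuple, first regulator
#' most significant, encodes the integer `r`.
#'
#' @param gene 1-based index of the target gene.
#' @param regulators strictly increasing vector of 1-based regulator indices
#'   (self-regulation is allowed).
#' @param outputs 0/1 vector of length `2^length(regulators)`.
#' @return an object of class `truth_table`.
#' @export
#' @examples
#' truth_table(1, c(2, 5), c(0, 0, 0, 1))  # x1' = x2 AND x5
truth_table <- function(gene, regulators, outputs) {
  gene <- as.integer(gene)
  regulators <- as.integer(regulators)
  if (length(regulators) < 1L) stop("gene ", gene, ": at least one regulator required")
  if (is.unsorted(regulators, strictly = TRUE)) {
    stop("gene ", gene, ": regulators must be strictly increasing")
  }
  if (length(outputs) != 2^length(regulators)) {
    stop("gene ", gene, ": outputs must have length 2^k = ",
         2^length(regulators), ", got ", length(outputs))
  }
  if (!all(outputs %in% c(0, 1))) stop("gene ", gene, ": outputs must be 0/1")
  structure(list(gene = gene, regulators = regulators,
                 outputs = as.integer(outputs)),
            class = "truth_table")
}

#' Construct a Boolean network with perturbation (BNp)
#'
#' A BNp updates all genes synchronously by their truth tables, except that at
#' each step every gene independently flips with probability `p`; whenever at
#' least one flip occurs the perturbation overrides the regulatory update.
#' Any `p > 0` makes the induced Markov chain on the 2^n gene activity
#' profiles irreducible and ergodic, so a unique steady-state distribution
#' exists.
#'
#' @param tables list of [truth_table()] objects, one per gene, covering gene
#'   indices `1..n` exactly once (any order; they are sorted).
#' @param p per-gene perturbation probability in `[0, 0.5)`; `p = 0` is
#'   accepted for deterministic analyses but forfeits ergodicity.
#' @return an object of class `bnp` with elements `n`, `tables`, `p`.
#' @export
bnp <- function(tables, p) {
  n <- length(tables)
  if (n < 1L) stop("need at least one gene")
  if (!all(vapply(tables, inherits, logical(1), "truth_table"))) {
    stop("`tables` must be a list of truth_table objects")
  }
  idx <- vapply(tables, function(tt) tt$gene, integer(1))
  if (!setequal(idx, seq_len(n)) || anyDuplicated(idx)) {
    stop("tables must cover gene indices 1..", n, " exactly once")
  }
  tables <- tables[order(idx)]
  for (tt in tables) {
    if (any(tt$regulators < 1L | tt$regulators > n)) {
      stop("gene ", tt$gene, ": regulator index outside 1..", n)
    }
  }
  if (!is.numeric(p) || length(p) != 1L || p < 0 || p >= 0.5) {
    stop("`p` must be a single probability in [0, 0.5)")
  }
  structure(list(n = n, tables = tables, p = p), class = "bnp")
}

#' @export
print.bnp <- function(x, ...) {
  cat("Boolean network with perturbation:", x$n, "genes, p =", x$p, "\n")
  for (tt in x$tables) {
    cat(sprintf("  x%d' = f(%s)  out=%s\n", tt$gene,
                paste0("x", tt$regulators, collapse = ","),
                paste0(tt$outputs, collapse = "")))
  }
  invisible(x)
}

#' Construct a probabilistic Boolean network (PBN)
#'
#' A PBN is a family of constituent BNps (contexts) sharing the gene set; at
#' each step, with probability `q` the governing context is redrawn from the
#' selection distribution `c` (possibly re-selecting the current one), and the
#' gene activity profile then transitions under the governing context's BNp
#' mechanism. `q = 1` gives the instantaneously random PBN, `q < 1` a
#' context-sensitive one.
#'
#' @param contexts list of [bnp()] objects sharing `n` and `p`.
#' @param q context switch probability in `(0, 1]`.
#' @param c selection probability vector, one entry per context, summing to 1.
#' @return an object of class `pbn`.
#' @export
pbn <- function(contexts, q, c) {
  m <- length(contexts)
  if (m < 1L) stop("need at least one context")
  if (!all(vapply(contexts, inherits, logical(1), "bnp"))) {
    stop("`contexts` must be a list of bnp objects")
  }
  ns <- vapply(contexts, function(b) b$n, integer(1))
  if (length(unique(ns)) != 1L) stop("all contexts must share the gene count")
  if (q <= 0 || q > 1) stop("`q` must be in (0, 1]")
  if (length(c) != m || any(c < 0) || abs(sum(c) - 1) > 1e-12) {
    stop("`c` must be a length-", m, " probability vector summing to 1")
  }
  structure(list(n = ns[1], m = m, contexts = contexts, q = q, c = as.numeric(c)),
            class = "pbn")
}

#' Evaluate a truth table on a gene activity profile
#'
#' @param tt a [truth_table()].
#' @param state full 0/1 profile of the network (length n).
#' @return the gene's next value, 0 or 1.
#' @export
evaluate_function <- function(tt, state) {
  if (any(tt$regulators > length(state))) stop("regulator index out of range")
  k <- length(tt$regulators)
  row <- sum(state[tt$regulators] * 2^((k - 1):0))
  tt$outputs[row + 1L]
}

#' Deterministic synchronous successor state
#'
#' Applies every gene's truth table simultaneously (the perturbation-free
#' update `f(x)`).
#'
#' @param net a [bnp()].
#' @param state 0/1 profile of length `net$n`.
#' @return the successor 0/1 profile.
#' @export
next_state_deterministic <- function(net, state) {
  vapply(net$tables, evaluate_function, integer(1), state = state)
}

#' Deterministic image of every state, as 1-based indices
#'
#' @param net a [bnp()].
#' @return integer vector `img` of length 2^n with `img[s]` the 1-based index
#'   of `f(x_s)`.
#' @export
state_images <- function(net) {
  n <- net$n
  S <- all_states(n)
  nxt <- matrix(0L, nrow(S), n)
  for (tt in net$tables) {
    k <- length(tt$regulators)
    rows <- as.integer(S[, tt$regulators, drop = FALSE] %*% 2^((k - 1):0))
    nxt[, tt$gene] <- tt$outputs[rows + 1L]
  }
  as.integer(nxt %*% 2^((n - 1):0)) + 1L
}

#' Transition probability matrix of a BNp
#'
#' The chain moves from `x` to `f(x)` with probability `(1-p)^n` (no gene
#' perturbed) and to `x XOR gamma` with probability `p^d (1-p)^(n-d)` for every
#' non-zero perturbation vector `gamma` of weight `d`. Probabilities for
#' coinciding destinations accumulate, so every row sums to exactly 1.
#'
#' @param net a [bnp()].
#' @return a dense `2^n x 2^n` row-stochastic matrix, rows and columns in
#'   `all_states` order.
#' @export
build_tpm_bnp <- function(net) {
  n <- net$n
  N <- 2^n
  p <- net$p
  img <- state_images(net)
  pc <- bit_counts(n)
  P <- matrix(0, N, N)
  for (s in seq_len(N)) {
    d <- pc[bitwXor(s - 1L, 0:(N - 1)) + 1L]
    row <- p^d * (1 - p)^(n - d)
    row[d == 0L] <- 0
    P[s, ] <- row
  }
  P[cbind(seq_len(N), img)] <- P[cbind(seq_len(N), img)] + (1 - p)^n
  stopifnot(max(abs(rowSums(P) - 1)) < 1e-12)
  P
}

#' Transition probability matrix of a PBN on joint (profile, context) states
#'
#' Joint states are ordered context-major: state `(x, y)` sits at row
#' `(y-1) * 2^n + index(x) + 1`. Within a step the context is resolved first
#' (with probability `q` redrawn from `c`, else kept) and the profile then
#' moves by the governing context's BNp row. With a single context this
#' reduces exactly to [build_tpm_bnp()].
#'
#' @param net a [pbn()].
#' @return a dense `m*2^n x m*2^n` row-stochastic matrix.
#' @export
build_tpm_pbn <- function(net) {
  n <- net$n; m <- net$m; N <- 2^n
  blocks <- lapply(net$contexts, build_tpm_bnp)
  P <- matrix(0, m * N, m * N)
  for (y in seq_len(m)) {
    rows <- (y - 1) * N + seq_len(N)
    for (yp in seq_len(m)) {
      w <- net$q * net$c[yp] + (1 - net$q) * (yp == y)
      if (w > 0) P[rows, (yp - 1) * N + seq_len(N)] <- w * blocks[[yp]]
    }
  }
  stopifnot(max(abs(rowSums(P) - 1)) < 1e-10)
  P
}

#' Stationary distribution of an ergodic transition matrix
#'
#' Solves the balance equations `pi^T P = pi^T` directly, replacing one
#' (redundant) balance equation with the normalization `sum(pi) = 1`. The
#' residual is checked against `tol`; failure indicates a non-ergodic chain
#' (e.g. `p = 0`).
#'
#' @param P row-stochastic matrix.
#' @param tol maximum allowed balance residual (max-norm), default `1e-10`.
#' @return the steady-state probability vector.
#' @export
steady_state <- function(P, tol = 1e-10) {
  N <- nrow(P)
  A <- t(P) - diag(N)
  A[N, ] <- 1
  b <- c(rep(0, N - 1), 1)
  pi <- tryCatch(solve(A, b), error = function(e) {
    stop("steady-state system is singular (chain not ergodic?): ",
         conditionMessage(e))
  })
  res <- max(abs(as.numeric(crossprod(P, pi)) - pi))
  if (res > tol) {
    stop(sprintf("steady-state residual %.3g exceeds tolerance %.3g", res, tol))
  }
  pi
}

#' Aggregated steady-state probability of the undesirable states
#'
#' @param pi steady-state vector.
#' @param U integer vector of 1-based undesirable state indices.
#' @return the undesirable mass `sum(pi[U])`.
#' @export
undesirable_mass <- function(pi, U) state_mass(pi, U)

#' Adjacency matrix of a network's regulatory graph
#'
#' @param net a [bnp()] (inferred or ground truth).
#' @return an `n x n` 0/1 matrix with entry `(i, j) = 1` iff gene `i` is a
#'   regulator of gene `j` (directed edge `i -> j`).
#' @export
adjacency <- function(net) {
  n <- net$n
  A <- matrix(0L, n, n)
  for (tt in net$tables) A[tt$regulators, tt$gene] <- 1L
  A
}
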