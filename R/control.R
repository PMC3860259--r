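#' Transition row under a control action
#'
#' The intervention flips the control gene before the transition: under action
#' `a = 1` the row of state `s` is replaced by the row of the state with the
#' control gene's bit toggled; under `a = 0` the row is unchanged.
#'
#' @param P transition matrix of the uncontrolled chain.
#' @param state 1-based state index.
#' @param action 0 (no intervention) or 1 (flip the control gene).
#' @param control_gene 1-based gene index; `n` is inferred from `ncol(P)`.
#' @return the controlled transition row.
#' @export
controlled_row <- function(P, state, action, control_gene) {
  if (!action %in% c(0, 1)) stop("`action` must be 0 or 1")
  if (action == 0) return(P[state, ])
  n <- as.integer(round(log2(ncol(P))))
  P[flip_permutation(n, control_gene)[state], ]
}

#' Transition matrix of the chain controlled by a stationary policy
#'
#' @param P uncontrolled transition matrix.
#' @param policy 0/1 vector over states; 1 means intervene in that state.
#' @param control_gene 1-based control gene index.
#' @return row-stochastic controlled matrix; equals `P` for the zero policy.
#' @export
controlled_tpm <- function(P, policy, control_gene) {
  N <- nrow(P)
  if (length(policy) != N || !all(policy %in% c(0, 1))) {
    stop("`policy` must be a 0/1 vector with one entry per state")
  }
  n <- as.integer(round(log2(N)))
  flip <- flip_permutation(n, control_gene)
  Pv <- P
  on <- which(policy == 1)
  if (length(on)) Pv[on, ] <- P[flip[on], , drop = FALSE]
  Pv
}

#' Steady-state shift of the undesirable mass under a control policy
#'
#' @param pi steady state of the uncontrolled chain.
#' @param pi_v steady state of the controlled chain.
#' @param U 1-based undesirable state indices.
#' @return the shift `sum(pi[U]) - sum(pi_v[U])`; positive when control
#'   reduces the undesirable mass.
#' @export
delta_shift <- function(pi, pi_v, U) state_mass(pi, U) - state_mass(pi_v, U)

#' Optimal stationary intervention by maximal steady-state alteration (MSSA)
#'
#' Finds the stationary deterministic policy (one action per state, action 1 =
#' flip the control gene) that minimizes the steady-state mass on the
#' undesirable states, equivalently maximizes the shift returned by
#' [delta_shift()]. The optimum over all stationary deterministic policies is
#' computed exactly by policy iteration on the average-reward Markov decision
#' process whose reward is the desirable-state indicator; since every
#' controlled chain is ergodic for `p > 0`, the gain of a policy is exactly its
#' desirable steady-state mass, and policy iteration terminates finitely at the
#' same optimum as the occupation-measure linear program it is dual to. Action
#' ties are resolved to 0 (no intervention). The returned shift is re-derived
#' from the extracted policy via [controlled_tpm()] and [steady_state()], so it
#' never depends on the inner solver's tolerance.
#'
#' @param net a [bnp()], or `NULL` when `P` is supplied directly.
#' @param U 1-based undesirable state indices (nonempty proper subset),
#'   e.g. from [marker_states()].
#' @param control_gene 1-based control gene index.
#' @param P optional precomputed transition matrix (saves rebuilding it when
#'   scanning many control genes on one network).
#' @param pi optional precomputed uncontrolled steady state.
#' @return object of class `mssa_policy`: list with `policy` (0/1 per state),
#'   `pi` (uncontrolled steady state), `pi_controlled`, `pi_U_before`,
#'   `pi_U_after`, `delta`, `iterations`.
#' @export
mssa_optimal_policy <- function(net, U, control_gene, P = NULL, pi = NULL) {
  if (is.null(P)) P <- build_tpm_bnp(net)
  N <- nrow(P)
  n <- as.integer(round(log2(N)))
  if (length(U) == 0L || length(U) >= N) {
    stop("`U` must be a nonempty proper subset of the state space")
  }
  if (control_gene < 1 || control_gene > n) stop("control gene out of range")
  if (is.null(pi)) pi <- steady_state(P)
  flip <- flip_permutation(n, control_gene)
  P1 <- P[flip, , drop = FALSE]
  reward <- rep(1, N)
  reward[U] <- 0
  a <- rep(0L, N)
  gain <- -Inf
  I_N <- diag(N)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    Pv <- P
    on <- which(a == 1L)
    if (length(on)) Pv[on, ] <- P1[on, , drop = FALSE]
    # evaluation: gain g and bias h (h[1] = 0) solve g + h = r + Pv h
    M <- cbind(1, (I_N - Pv)[, -1L, drop = FALSE])
    u <- solve(M, reward)
    g_new <- u[1L]
    h <- c(0, u[-1L])
    q0 <- as.numeric(P %*% h)
    q1 <- as.numeric(P1 %*% h)
    a_new <- ifelse(q1 > q0 + 1e-10, 1L, 0L)
    if (all(a_new == a) || iter >= 200L) { gain <- g_new; break }
    if (g_new < gain - 1e-12) { break }  # numerical guard: never accept a worse policy
    a <- a_new
    gain <- g_new
  }
  Pv <- controlled_tpm(P, a, control_gene)
  pi_v <- steady_state(Pv)
  structure(list(policy = a,
                 pi = pi,
                 pi_controlled = pi_v,
                 pi_U_before = state_mass(pi, U),
                 pi_U_after = state_mass(pi_v, U),
                 delta = delta_shift(pi, pi_v, U),
                 iterations = iter),
            class = "mssa_policy")
}

#' @export
print.mssa_policy <- function(x, ...) {
  cat(sprintf(paste0("MSSA stationary policy: intervene in %d/%d states\n",
                     "  undesirable mass %.4f -> %.4f (shift %.4f)\n"),
              sum(x$policy), length(x$policy),
              x$pi_U_before, x$pi_U_after, x$delta))
  invisible(x)
}
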