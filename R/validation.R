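#' Hamming distance between regulatory topologies
#'
#' @param A_true,A_inf 0/1 adjacency matrices on the same gene set (entry
#'   `(i, j) = 1` iff edge `i -> j`).
#' @param normalize divide by the number of edges in `A_true` (the usual
#'   reporting convention).
#' @return non-negative real.
#' @export
mu_hamming <- function(A_true, A_inf, normalize = TRUE) {
  if (!all(dim(A_true) == dim(A_inf))) stop("adjacency matrices differ in size")
  d <- sum(abs(A_true - A_inf))
  if (normalize) d / sum(A_true) else d
}

#' L1 distance between steady-state distributions
#'
#' @param pi,omega steady-state vectors of equal length.
#' @return value in `[0, 2]`.
#' @export
mu_steady_state <- function(pi, omega) {
  if (length(pi) != length(omega)) stop("steady-state vectors differ in length")
  sum(abs(pi - omega))
}

#' Controllability distance between a true network and an inferred one
#'
#' Designs the MSSA policy on the inferred network and on the true network,
#' applies BOTH to the true network, and reports the excess undesirable
#' steady-state mass incurred by using the inferred network's policy instead
#' of the optimal one. Because the true network's own policy is optimal, the
#' distance is always >= 0, and 0 when the two policies agree on the recurrent
#' states.
#'
#' @param true_net the ground-truth [bnp()].
#' @param inferred an inferred [bnp()] on the same genes.
#' @param marker 1-based marker gene index.
#' @param undesirable_value marker value (0/1) defining the undesirable states.
#' @param control_gene 1-based control gene index.
#' @param P_true,pi_true,opt_true optional precomputed transition matrix,
#'   steady state, and [mssa_optimal_policy()] of the true network (reused
#'   across algorithms in ensemble runs).
#' @return list of class `validation_report`: `mu_ctrl`, `pi_U_original`,
#'   `pi_U_opt`, `pi_U_inferred_policy`, and the two policies.
#' @export
mu_controllability <- function(true_net, inferred, marker, undesirable_value,
                               control_gene, P_true = NULL, pi_true = NULL,
                               opt_true = NULL) {
  if (true_net$n != inferred$n) stop("gene sets of the two networks differ")
  n <- true_net$n
  U <- marker_states(n, marker, undesirable_value)
  if (is.null(P_true)) P_true <- build_tpm_bnp(true_net)
  if (is.null(pi_true)) pi_true <- steady_state(P_true)
  if (is.null(opt_true)) {
    opt_true <- mssa_optimal_policy(true_net, U, control_gene,
                                    P = P_true, pi = pi_true)
  }
  opt_inf <- mssa_optimal_policy(inferred, U, control_gene)
  pi_cross <- steady_state(controlled_tpm(P_true, opt_inf$policy, control_gene))
  structure(list(
    mu_ctrl = state_mass(pi_cross, U) - opt_true$pi_U_after,
    pi_U_original = state_mass(pi_true, U),
    pi_U_opt = opt_true$pi_U_after,
    pi_U_inferred_policy = state_mass(pi_cross, U),
    policy_true = opt_true$policy,
    policy_inferred = opt_inf$policy
  ), class = "validation_report")
}

#' Ensemble experiment: inference validity over random networks
#'
#' For each replicate network drawn from the random-BNp ensemble, simulates a
#' time series at each sample size in `M_values`, runs each inference
#' algorithm, and computes the three validity semi-metrics (topology
#' [mu_hamming()], dynamics [mu_steady_state()], controllability
#' [mu_controllability()]) plus the controlled undesirable masses, all against
#' the ground-truth network. Everything is driven by one seed, so results are
#' exactly reproducible.
#'
#' @param n,K,p random-network ensemble parameters (see
#'   [generate_random_bnp()]).
#' @param n_networks number of replicate networks.
#' @param M_values integer vector of observed-transition counts; may be empty
#'   to compute only the per-network baseline and optimal-control masses.
#' @param algorithms character subset of
#'   `c("reveal", "bic", "mdl", "umdl", "bestfit")`; may be empty.
#' @param marker,undesirable_value marker gene and its undesirable value
#'   (defaults: gene 1 down-regulated).
#' @param control_gene control gene (default: the last gene).
#' @param seed integer seed.
#' @return list of class `bnp_experiment`: `networks` (one row per network:
#'   `pi_U_original`, `pi_U_opt`, `delta_opt`) and `results` (one row per
#'   network x M x algorithm: `mu_ham`, `mu_ss`, `mu_ctrl`, `pi_U_ctrl`,
#'   `n_edges`).
#' @export
run_experiment <- function(n = 7, K = 3, p = 0.01, n_networks = 100,
                           M_values = c(10, 30, 50), algorithms = "bestfit",
                           marker = 1, undesirable_value = 0,
                           control_gene = n, seed = 1) {
  stopifnot(n_networks >= 1, all(M_values >= 1))
  set.seed(seed)
  U <- marker_states(n, marker, undesirable_value)
  net_rows <- vector("list", n_networks)
  res_rows <- list()
  for (r in seq_len(n_networks)) {
    net <- generate_random_bnp(n, K, p)
    P <- build_tpm_bnp(net)
    pi0 <- steady_state(P)
    opt <- mssa_optimal_policy(net, U, control_gene, P = P, pi = pi0)
    net_rows[[r]] <- data.frame(network = r,
                                pi_U_original = state_mass(pi0, U),
                                pi_U_opt = opt$pi_U_after,
                                delta_opt = opt$delta)
    A_true <- adjacency(net)
    for (M in M_values) {
      series <- generate_time_series(net, M)
      for (algo in algorithms) {
        inf <- infer_network(series, method = algo, K = K, p = p)
        pi_inf <- steady_state(build_tpm_bnp(inf))
        rep_ctrl <- mu_controllability(net, inf, marker, undesirable_value,
                                       control_gene, P_true = P,
                                       pi_true = pi0, opt_true = opt)
        res_rows[[length(res_rows) + 1L]] <- data.frame(
          network = r, M = M, algorithm = algo,
          mu_ham = mu_hamming(A_true, adjacency(inf)),
          mu_ss = mu_steady_state(pi0, pi_inf),
          mu_ctrl = rep_ctrl$mu_ctrl,
          pi_U_ctrl = rep_ctrl$pi_U_inferred_policy,
          n_edges = sum(adjacency(inf)))
      }
    }
  }
  structure(list(
    networks = do.call(rbind, net_rows),
    results = if (length(res_rows)) do.call(rbind, res_rows) else NULL,
    config = list(n = n, K = K, p = p, n_networks = n_networks,
                  M_values = M_values, algorithms = algorithms,
                  marker = marker, undesirable_value = undesirable_value,
                  control_gene = control_gene, seed = seed)
  ), class = "bnp_experiment")
}

#' Ensemble means and standard deviations of an experiment
#'
#' @param exp a [run_experiment()] result.
#' @return data frame with one row per (algorithm, M): means and sds of
#'   `mu_ham`, `mu_ss`, `mu_ctrl`, `pi_U_ctrl`, `n_edges` across networks.
#' @export
summarize_experiment <- function(exp) {
  if (is.null(exp$results)) return(NULL)
  res <- exp$results
  agg <- function(f, suffix) {
    out <- stats::aggregate(res[, c("mu_ham", "mu_ss", "mu_ctrl",
                                    "pi_U_ctrl", "n_edges")],
                            by = res[, c("algorithm", "M")], FUN = f)
    names(out)[-(1:2)] <- paste0(names(out)[-(1:2)], suffix)
    out
  }
  merge(agg(mean, "_mean"), agg(stats::sd, "_sd"),
        by = c("algorithm", "M"), sort = TRUE)
}

#' @export
print.bnp_experiment <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("Random-BNp experiment: n=%d K=%d p=%g, %d networks\n",
              cfg$n, cfg$K, cfg$p, cfg$n_networks))
  cat(sprintf("  mean pi_U original  %.4f (sd %.4f)\n",
              mean(x$networks$pi_U_original), stats::sd(x$networks$pi_U_original)))
  cat(sprintf("  mean pi_U optimal   %.4f (sd %.4f)\n",
              mean(x$networks$pi_U_opt), stats::sd(x$networks$pi_U_opt)))
  if (!is.null(x$results)) {
    cat("  per-(algorithm, M) summaries: see summarize_experiment()\n")
  }
  invisible(x)
}
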