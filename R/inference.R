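# Shared machinery ------------------------------------------------------------

# all candidate regulator subsets of 1..n with sizes 1..K, ordered by size
# then lexicographically -- the sparsity-first tie-break order used by every
# inference rule below
candidate_subsets <- function(n, K) {
  out <- list()
  for (k in seq_len(min(K, n))) {
    cmb <- utils::combn(n, k)
    out <- c(out, lapply(seq_len(ncol(cmb)), function(j) cmb[, j]))
  }
  out
}

# binary entropy (bits) of counts; 0 log 0 = 0
entropy_bits <- function(counts) {
  tot <- sum(counts)
  if (tot == 0) return(0)
  p <- counts[counts > 0] / tot
  -sum(p * log2(p))
}

#' Tally observed transitions for one target gene and regulator subset
#'
#' Counts, over all consecutive state pairs within each series (never across
#' series boundaries), how often the target gene's next value is 0 or 1 for
#' each input pattern of the candidate regulator subset `W` (first regulator
#' most significant).
#'
#' @param series list of time-series matrices or a single matrix.
#' @param target 1-based target gene index.
#' @param W vector of 1-based regulator indices (increasing).
#' @return object of class `transition_counts`: list with integer vectors `n0`
#'   and `n1` of length `2^length(W)`, plus `M` (total transitions), `target`,
#'   `W`.
#' @export
count_transitions <- function(series, target, W) {
  tp <- transition_pairs(series)
  count_transitions_pairs(tp$from, tp$to, target, W)
}

# same, from pre-stacked transition pairs (hot loop of every inference rule)
count_transitions_pairs <- function(from, to, target, W) {
  k <- length(W)
  R <- 2^k
  w <- as.integer(from[, W, drop = FALSE] %*% 2^((k - 1):0)) + 1L
  y <- to[, target]
  n1 <- tabulate(w[y == 1L], nbins = R)
  n0 <- tabulate(w[y == 0L], nbins = R)
  structure(list(n0 = n0, n1 = n1, M = length(y),
                 target = target, W = W),
            class = "transition_counts")
}

#' Best-fit error of a candidate regulator subset
#'
#' The minimum number of observed transitions any Boolean function on the
#' subset must misclassify: for each input pattern the minority next-value
#' count is unavoidable.
#'
#' @param counts a [count_transitions()] result.
#' @return non-negative integer error.
#' @export
best_fit_error <- function(counts) {
  sum(pmin(counts$n0, counts$n1))
}

#' Fit a (possibly partially defined) Boolean function from transition counts
#'
#' Observed input patterns get their majority next-value (tie -> 0). Patterns
#' never observed are filled with the target gene's overall majority
#' next-value across all transitions (tie -> 0), and the number of filled rows
#' is recorded so the fill rate can be audited.
#'
#' @param counts a [count_transitions()] result.
#' @return list with `outputs` (0/1 vector of length `2^k`) and `n_filled`
#'   (count of unseen patterns).
#' @export
fit_function <- function(counts) {
  seen <- counts$n0 + counts$n1 > 0L
  out <- as.integer(counts$n1 > counts$n0)
  fill <- as.integer(sum(counts$n1) > sum(counts$n0))
  out[!seen] <- fill
  list(outputs = out, n_filled = sum(!seen))
}

# build the inferred bnp from per-gene winning subsets
assemble_network <- function(from, to, winners, n, p, method) {
  tables <- vector("list", n)
  info <- vector("list", n)
  for (i in seq_len(n)) {
    W <- winners[[i]]$W
    cnt <- count_transitions_pairs(from, to, i, W)
    ff <- fit_function(cnt)
    tables[[i]] <- truth_table(i, W, ff$outputs)
    info[[i]] <- list(W = W, score = winners[[i]]$score,
                      k = length(W), n_filled = ff$n_filled)
  }
  net <- bnp(tables, p)
  attr(net, "inference") <- list(method = method, genes = info)
  net
}

# generic per-gene subset scan: score_fun(counts) -> numeric, lower is better;
# strict improvement keeps the earliest (smallest, lexicographically first)
# minimizer, realizing the most-sparse tie-break
scan_subsets <- function(from, to, target, subsets, score_fun) {
  best <- NULL
  best_score <- Inf
  for (W in subsets) {
    cnt <- count_transitions_pairs(from, to, target, W)
    s <- score_fun(cnt)
    if (s < best_score - 1e-12) {
      best_score <- s
      best <- W
    }
  }
  list(W = best, score = best_score)
}

# Inference algorithms ---------------------------------------------------------

#' Infer a network by the Best-Fit extension
#'
#' Per gene, exhaustively scores every regulator subset of size `1..K` by its
#' [best_fit_error()]; among all subsets attaining the global minimum error the
#' smallest (then lexicographically first) is selected, and the function is
#' completed by [fit_function()].
#'
#' @param series list of time-series matrices.
#' @param K maximum in-degree searched.
#' @param p perturbation probability recorded on the inferred network (the
#'   data's assumed noise level; it is not estimated).
#' @return an inferred [bnp()] with an `"inference"` attribute recording each
#'   gene's winning subset, score, and unseen-row fill count.
#' @export
infer_best_fit <- function(series, K = 3, p = 0.01) {
  tp <- transition_pairs(series)
  if (nrow(tp$from) == 0L) stop("empty time series")
  n <- ncol(tp$from)
  subsets <- candidate_subsets(n, K)
  winners <- lapply(seq_len(n), function(i) {
    scan_subsets(tp$from, tp$to, i, subsets, best_fit_error)
  })
  assemble_network(tp$from, tp$to, winners, n, p, "bestfit")
}

#' Infer a network by REVEAL (mutual-information consistency)
#'
#' Per gene, scans subsets in sparsity-first order and accepts the first whose
#' plug-in mutual information with the gene's next value reaches the next
#' value's empirical entropy (in-sample determinism) within `eps` bits. If no
#' subset of size up to `K` is consistent, the size-`K` subset with maximal
#' mutual information (lexicographically first on ties) is returned. Functions
#' are completed by [fit_function()].
#'
#' @inheritParams infer_best_fit
#' @param eps consistency slack in bits, default `1e-9`.
#' @return an inferred [bnp()].
#' @export
infer_reveal <- function(series, K = 3, p = 0.01, eps = 1e-9) {
  tp <- transition_pairs(series)
  if (nrow(tp$from) == 0L) stop("empty time series")
  n <- ncol(tp$from)
  subsets <- candidate_subsets(n, K)
  sizes <- lengths(subsets)
  winners <- lapply(seq_len(n), function(i) {
    best_W <- NULL
    best_ce <- Inf   # conditional entropy: MI = H(target') - ce
    for (j in seq_along(subsets)) {
      W <- subsets[[j]]
      cnt <- count_transitions_pairs(tp$from, tp$to, i, W)
      ce <- conditional_entropy_bits(cnt)
      if (ce <= eps) return(list(W = W, score = ce))  # consistent: accept
      if (sizes[j] == K && ce < best_ce - 1e-12) {
        best_ce <- ce
        best_W <- W
      }
    }
    list(W = best_W, score = best_ce)
  })
  assemble_network(tp$from, tp$to, winners, n, p, "reveal")
}

#' Empirical conditional entropy of a target's next value given a subset
#'
#' `H(target' | X_W)` in bits, the plug-in estimate over the observed input
#' patterns; the mutual information used by REVEAL is
#' `H(target') - H(target' | X_W)`.
#'
#' @param counts a [count_transitions()] result.
#' @return conditional entropy in bits.
#' @export
conditional_entropy_bits <- function(counts) {
  m_w <- counts$n0 + counts$n1
  idx <- which(m_w > 0L)
  if (length(idx) == 0L) return(0)
  sum(vapply(idx, function(w) {
    entropy_bits(c(counts$n0[w], counts$n1[w])) * m_w[w]
  }, numeric(1))) / counts$M
}

#' Penalized description-length score of a regulator subset
#'
#' `score = L_data + lambda * L_model` with `L_data = M * H(target' | X_W)`
#' bits. The model length is `k log2(n) + 2^k` bits for the `"mdl"` variant
#' (regulator identities plus the truth-table column) and `(2^k / 2) log2(M)`
#' for the `"bic"` variant. Lower is better.
#'
#' @param counts a [count_transitions()] result.
#' @param n gene count (regulator-identity code length).
#' @param lambda regularization weight on the model length.
#' @param variant `"mdl"` or `"bic"`.
#' @return the score in bits.
#' @export
mdl_score <- function(counts, n, lambda, variant = c("mdl", "bic")) {
  variant <- match.arg(variant)
  k <- length(counts$W)
  M <- counts$M
  L_data <- M * conditional_entropy_bits(counts)
  L_model <- switch(variant,
                    mdl = k * log2(n) + 2^k,
                    bic = (2^k / 2) * log2(M))
  L_data + lambda * L_model
}

#' Infer a network by penalized description length (MDL or BIC)
#'
#' Per gene, minimizes [mdl_score()] over all subsets of size `1..K`; ties go
#' to the smaller subset, then lexicographic order. Functions are completed by
#' [fit_function()].
#'
#' @inheritParams infer_best_fit
#' @param lambda regularization weight; 0.3 for `"mdl"` and 0.5 for `"bic"`
#'   are the defaults used throughout the experiments.
#' @param variant `"mdl"` or `"bic"`.
#' @return an inferred [bnp()].
#' @export
infer_mdl <- function(series, K = 3, p = 0.01,
                      lambda = if (variant == "bic") 0.5 else 0.3,
                      variant = c("mdl", "bic")) {
  variant <- match.arg(variant)
  force(lambda)
  tp <- transition_pairs(series)
  if (nrow(tp$from) == 0L) stop("empty time series")
  n <- ncol(tp$from)
  subsets <- candidate_subsets(n, K)
  winners <- lapply(seq_len(n), function(i) {
    scan_subsets(tp$from, tp$to, i, subsets,
                 function(cnt) mdl_score(cnt, n, lambda, variant))
  })
  assemble_network(tp$from, tp$to, winners, n, p, variant)
}

#' Bernoulli normalized-maximum-likelihood parametric complexity
#'
#' `COMP(m) = log2 sum_{j=0}^{m} C(m, j) (j/m)^j ((m-j)/m)^(m-j)` bits (with
#' `0^0 = 1`); the tuning-free model penalty used by the universal-MDL rule.
#' Evaluated in log space for numerical stability.
#'
#' @param m number of observations under one input pattern (`m >= 0`).
#' @return the complexity in bits.
#' @export
nml_complexity <- function(m) {
  if (m == 0) return(0)
  j <- 0:m
  lt <- lchoose(m, j) +
    ifelse(j == 0, 0, j * log(j / m)) +
    ifelse(j == m, 0, (m - j) * log((m - j) / m))
  mx <- max(lt)
  (mx + log(sum(exp(lt - mx)))) / log(2)
}

#' Infer a network by universal MDL (normalized maximum likelihood)
#'
#' Per gene, minimizes the universal code length
#' `sum_w [m_w H_w + COMP(m_w)] + k log2(n)` over subsets of size `1..K`,
#' where `H_w` is the empirical entropy of the next values under pattern `w`,
#' `COMP` the Bernoulli NML parametric complexity of [nml_complexity()], and
#' `k log2(n)` the code naming the `k` regulators among `n` genes. Unlike the
#' BIC/MDL scores there is no tuning weight: the data and parameter costs come
#' from the NML code and the structure cost is the plain identity code, which
#' is what makes this rule the most conservative about adding regulators at
#' small sample sizes. Ties go to the smaller subset, then lexicographic.
#' Functions by [fit_function()].
#'
#' @inheritParams infer_best_fit
#' @return an inferred [bnp()].
#' @export
infer_umdl <- function(series, K = 3, p = 0.01) {
  tp <- transition_pairs(series)
  if (nrow(tp$from) == 0L) stop("empty time series")
  n <- ncol(tp$from)
  subsets <- candidate_subsets(n, K)
  comp_cache <- new.env(parent = emptyenv())
  comp <- function(m) {
    key <- as.character(m)
    if (is.null(comp_cache[[key]])) comp_cache[[key]] <- nml_complexity(m)
    comp_cache[[key]]
  }
  umdl_score <- function(cnt) {
    m_w <- cnt$n0 + cnt$n1
    idx <- which(m_w > 0L)
    sum(vapply(idx, function(w) {
      entropy_bits(c(cnt$n0[w], cnt$n1[w])) * m_w[w] + comp(m_w[w])
    }, numeric(1))) + length(cnt$W) * log2(n)
  }
  winners <- lapply(seq_len(n), function(i) {
    scan_subsets(tp$from, tp$to, i, subsets, umdl_score)
  })
  assemble_network(tp$from, tp$to, winners, n, p, "umdl")
}

#' Run one of the five inference algorithms by name
#'
#' @param series list of time-series matrices.
#' @param method one of `"reveal"`, `"bestfit"`, `"bic"`, `"mdl"`, `"umdl"`.
#' @param K maximum in-degree.
#' @param p perturbation probability stamped on the inferred network.
#' @param lambda regularization weight for `"bic"`/`"mdl"` (defaults 0.5/0.3).
#' @return an inferred [bnp()].
#' @export
infer_network <- function(series,
                          method = c("bestfit", "reveal", "bic", "mdl", "umdl"),
                          K = 3, p = 0.01, lambda = NULL) {
  method <- match.arg(method)
  switch(method,
         bestfit = infer_best_fit(series, K, p),
         reveal = infer_reveal(series, K, p),
         bic = infer_mdl(series, K, p,
                         lambda = if (is.null(lambda)) 0.5 else lambda,
                         variant = "bic"),
         mdl = infer_mdl(series, K, p,
                         lambda = if (is.null(lambda)) 0.3 else lambda,
                         variant = "mdl"),
         umdl = infer_umdl(series, K, p))
}
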