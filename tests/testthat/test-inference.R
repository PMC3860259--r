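test_that("transition counting respects series boundaries", {
  s1 <- matrix(c(0, 0,
                 1, 0,
                 1, 1), ncol = 2, byrow = TRUE)
  s2 <- matrix(c(1, 1,
                 0, 1), ncol = 2, byrow = TRUE)
  cnt <- count_transitions(list(s1, s2), target = 1, W = 1)
  expect_identical(cnt$M, 3L)             # 2 + 1, never bridging the gap
  # hand tally: from x1=0 -> next x1=1 once; from x1=1 -> next 1 once, 0 once
  expect_identical(cnt$n0, c(0L, 1L))
  expect_identical(cnt$n1, c(1L, 1L))
  one <- count_transitions(matrix(0L, 11, 2), target = 2, W = c(1, 2))
  expect_identical(one$M, 10L)
  two <- count_transitions(list(matrix(0L, 6, 2), matrix(0L, 6, 2)), 2, 1)
  expect_identical(two$M, 10L)
})

test_that("best-fit error equals the brute-force function-enumeration minimum", {
  pure <- structure(list(n0 = c(3L, 0L), n1 = c(0L, 5L), M = 8L,
                         target = 1L, W = 1L), class = "transition_counts")
  expect_identical(best_fit_error(pure), 0L)
  mixed <- structure(list(n0 = c(2L, 1L), n1 = c(1L, 0L), M = 4L,
                          target = 1L, W = 1L), class = "transition_counts")
  expect_identical(best_fit_error(mixed), 1L)
  set.seed(41)
  for (k in 1:3) {
    for (trial in 1:10) {
      cnt <- structure(list(n0 = as.integer(rpois(2^k, 2)),
                            n1 = as.integer(rpois(2^k, 2))),
                       class = "transition_counts")
      cnt$M <- sum(cnt$n0) + sum(cnt$n1)
      expect_identical(best_fit_error(cnt), as.integer(oracle_min_error(cnt)))
    }
  }
})

test_that("function fitting uses majority with tie -> 0 and gene-majority fill", {
  cnt <- structure(list(n0 = c(1L, 0L, 2L, 0L), n1 = c(1L, 3L, 0L, 0L),
                        M = 7L, target = 1L, W = c(1L, 2L)),
                   class = "transition_counts")
  ff <- fit_function(cnt)
  # pattern 00: tie -> 0; 01: majority 1; 10: majority 0;
  # 11 unseen: gene majority is 1 (4 ones vs 3 zeros)
  expect_identical(ff$outputs, c(0L, 1L, 0L, 1L))
  expect_identical(ff$n_filled, 1L)
  empty <- structure(list(n0 = c(0L, 0L), n1 = c(0L, 0L), M = 0L,
                          target = 1L, W = 1L), class = "transition_counts")
  expect_identical(fit_function(empty)$outputs, c(0L, 0L))
})

test_that("Best-Fit and REVEAL recover minimal networks from full coverage", {
  for (n in 3:4) {
    net <- xor_chain_net(n)
    series <- full_coverage_series(net)
    for (method in c("bestfit", "reveal")) {
      inf <- infer_network(series, method = method, K = 3, p = net$p)
      expect_equal(mu_hamming(adjacency(net), adjacency(inf)), 0,
                   info = paste(method, n))
      for (i in seq_len(n)) {
        expect_identical(inf$tables[[i]]$outputs, net$tables[[i]]$outputs)
      }
    }
  }
})

test_that("a constant target gene gets the first sparsest consistent subset", {
  set.seed(55)
  series <- list(cbind(rep(0L, 12), sample(0:1, 12, replace = TRUE),
                       sample(0:1, 12, replace = TRUE)))
  for (method in c("bestfit", "reveal", "bic", "mdl", "umdl")) {
    inf <- infer_network(series, method = method, K = 2, p = 0.01)
    expect_identical(inf$tables[[1]]$regulators, 1L, info = method)
    expect_identical(inf$tables[[1]]$outputs, c(0L, 0L), info = method)
  }
})

test_that("description-length scores follow their stated formulas", {
  # deterministic data: only the model term remains
  cnt <- count_transitions(matrix(c(0, 1, 0, 1, 0) , ncol = 1), 1, 1)
  expect_equal(conditional_entropy_bits(cnt), 0)
  expect_equal(mdl_score(cnt, n = 7, lambda = 0.3, variant = "mdl"),
               0.3 * (log2(7) + 2), tolerance = 1e-12)
  expect_equal(mdl_score(cnt, n = 7, lambda = 0.5, variant = "bic"),
               0.5 * (2 / 2) * log2(4), tolerance = 1e-12)
  # noisy pattern: L_data = M * H(target' | W)
  cnt2 <- structure(list(n0 = c(3L, 0L), n1 = c(1L, 4L), M = 8L,
                         target = 1L, W = 1L), class = "transition_counts")
  h <- -(3 / 4) * log2(3 / 4) - (1 / 4) * log2(1 / 4)
  expect_equal(mdl_score(cnt2, n = 5, lambda = 0, variant = "mdl"), 4 * h,
               tolerance = 1e-12)
})

test_that("penalty weight controls sparsity in the expected directions", {
  net <- xor_chain_net(4)
  series <- full_coverage_series(net)
  # huge lambda: every gene collapses to a single regulator
  inf_big <- infer_mdl(series, K = 3, p = net$p, lambda = 1e6, variant = "mdl")
  expect_true(all(vapply(inf_big$tables,
                         function(tt) length(tt$regulators), integer(1)) == 1L))
  # lambda = 0: pure likelihood recovers the generating sets (data are exact)
  inf0 <- infer_mdl(series, K = 3, p = net$p, lambda = 0, variant = "mdl")
  expect_equal(mu_hamming(adjacency(net), adjacency(inf0)), 0)
})

test_that("Bernoulli NML parametric complexity matches closed-form values", {
  expect_equal(nml_complexity(0), 0)
  expect_equal(nml_complexity(1), 1)                # log2(1 + 1)
  expect_equal(nml_complexity(2), log2(2.5), tolerance = 1e-12)
  # monotone increasing in the sample count
  comps <- vapply(1:30, nml_complexity, numeric(1))
  expect_true(all(diff(comps) > 0))
})

test_that("the universal-MDL score rewards genuinely predictive regulators", {
  net <- xor_chain_net(4)
  series <- full_coverage_series(net)
  tp <- transition_pairs(series)
  # gene 2 = XOR(x1, x2): an uninformative singleton vs the true pair
  umdl <- function(W) {
    cnt <- count_transitions(series, target = 2, W = W)
    m_w <- cnt$n0 + cnt$n1
    sum(vapply(which(m_w > 0), function(w) {
      p1 <- cnt$n1[w] / m_w[w]
      h <- if (p1 %in% c(0, 1)) 0 else -p1 * log2(p1) - (1 - p1) * log2(1 - p1)
      m_w[w] * h + nml_complexity(m_w[w])
    }, numeric(1)))
  }
  expect_lt(umdl(c(1, 2)), umdl(3))
  inf <- infer_umdl(series, K = 3, p = net$p)
  expect_identical(inf$tables[[2]]$regulators, c(1L, 2L))
})

test_that("adjacency encodes regulator -> target edges", {
  mel <- melanoma_network()
  A <- adjacency(mel)
  expect_identical(which(A[, 3] == 1L), 7L)     # S100P regulated only by MART1
  expect_identical(A[7, 7], 1L)                 # MART1 self-loop
  expect_identical(adjacency(identity_net(4)), diag(1L, 4))
  # disjoint regulator sets: Hamming = total edge count of both networks
  n1 <- identity_net(3)
  n2 <- bnp(list(truth_table(1, 2, c(0L, 1L)), truth_table(2, 3, c(0L, 1L)),
                 truth_table(3, 1, c(0L, 1L))), 0.01)
  expect_equal(mu_hamming(adjacency(n1), adjacency(n2), normalize = FALSE), 6)
})

test_that("all five algorithms return valid networks within the degree bound", {
  set.seed(61)
  net <- generate_random_bnp(5, K = 3, p = 0.05)
  series <- generate_time_series(net, M = 25)
  for (method in c("reveal", "bic", "mdl", "umdl", "bestfit")) {
    inf <- infer_network(series, method = method, K = 3, p = 0.05)
    expect_s3_class(inf, "bnp")
    ks <- vapply(inf$tables, function(tt) length(tt$regulators), integer(1))
    expect_true(all(ks >= 1 & ks <= 3), info = method)
    expect_identical(attr(inf, "inference")$method,
                     switch(method, bic = "bic", mdl = "mdl", method))
  }
  expect_error(infer_best_fit(list(matrix(0L, 1, 5))), "empty")
})
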