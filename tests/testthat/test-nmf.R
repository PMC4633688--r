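test_that("KL divergence matches the definition and hand values", {
  # identity
  W <- matrix(runif(6, 0.5, 1), 3); H <- matrix(runif(8, 0.5, 1), 2)
  X <- W %*% H
  expect_equal(kl_divergence(X, W, H), 0, tolerance = 1e-12)
  # hand arithmetic: 2 log 2 - 2 + 1
  expect_equal(kl_divergence(matrix(2), matrix(1), matrix(1)),
               2 * log(2) - 1, tolerance = 1e-12)
  # zero fit against positive data is infinite
  expect_identical(kl_divergence(matrix(1), matrix(0), matrix(0)), Inf)
  # Gibbs inequality and loop-oracle agreement on random instances
  set.seed(41)
  for (k in 1:5) {
    X <- matrix(rpois(24, 2), 6, 4)
    W <- matrix(runif(12, 0.1, 1), 6, 2)
    H <- matrix(runif(8, 0.1, 1), 2, 4)
    expect_gte(kl_divergence(X, W, H), 0)
    expect_equal(kl_divergence(X, W, H), oracle_kl(X, W, H),
                 tolerance = 1e-12)
  }
})

test_that("regularization penalties follow their closed forms", {
  W <- matrix(0.7, 3, 2)
  H <- rbind(c(1, 0, 0), c(0, 2, 0))
  expect_equal(regularization_value(W, H, c = 0.7)[["F1"]], 0)
  expect_equal(regularization_value(W, H, alpha = 0)[["F2"]],
               0.5 * sum(H^2))
  # one-hot rows: ||h||_2^2 = ||h||_1^2, so F2 = (1 - alpha^2)/2 * sum h^2
  alpha <- 0.5
  expect_equal(regularization_value(W, H, alpha = alpha)[["F2"]],
               0.5 * (1 - alpha^2) * sum(H^2))
  W2 <- matrix(c(0, 1, 2, 3), 2)
  expect_equal(regularization_value(W2, H, c = 1)[["F1"]],
               0.5 * sum((c(0, 1, 2, 3) - 1)^2))
})

test_that("one multiplicative update step matches the Lee-Seung formulas", {
  set.seed(7)
  X <- matrix(rpois(9, 3) + 1, 3, 3)
  cfg <- nmf_config(rank = 2L, max_iter = 1L, seed = 99L)
  fit <- factorize(X, cfg)
  # replicate the documented seeded initialization
  set.seed(99L)
  W <- matrix(runif(6), 3, 2); H <- matrix(runif(6), 2, 3)
  s <- mean(X) / mean(W %*% H)
  W <- W * sqrt(s); H <- H * sqrt(s)
  # hand-applied updates (loops over the printed formulas)
  WH <- W %*% H
  Wn <- W
  for (i in 1:3) for (a in 1:2)
    Wn[i, a] <- W[i, a] * sum(H[a, ] * X[i, ] / WH[i, ]) / sum(H[a, ])
  WH <- Wn %*% H
  Hn <- H
  for (a in 1:2) for (j in 1:3)
    Hn[a, j] <- H[a, j] * sum(Wn[, a] * X[, j] / WH[, j]) / sum(Wn[, a])
  expect_equal(unname(fit$W), Wn, tolerance = 1e-9)
  expect_equal(unname(fit$H), Hn, tolerance = 1e-9)
})

test_that("unregularized updates never increase the objective and keep factors nonnegative", {
  set.seed(11)
  for (k in 1:3) {
    X <- matrix(rpois(20 * 30, 1.5), 20, 30)
    fit <- factorize(X, nmf_config(rank = 3L, max_iter = 150L, seed = k))
    tr <- fit$objective_trace
    expect_true(all(diff(tr) <= 1e-10 * pmax(abs(tr[-length(tr)]), 1)))
    expect_true(all(fit$W >= 0) && all(fit$H >= 0))
  }
})

test_that("exact low-rank matrices are recovered to tiny divergence", {
  for (seed in 1:5) {
    set.seed(seed)
    W0 <- matrix(runif(20 * 3, 0.2, 1), 20)
    H0 <- matrix(runif(3 * 30, 0.2, 1), 3)
    X <- W0 %*% H0
    fit <- factorize(X, nmf_config(rank = 3L, tol = 1e-14,
                                   max_iter = 2000L, seed = seed))
    expect_lt(kl_divergence(X, fit$W, fit$H), 1e-6)
  }
})

test_that("factorize is deterministic given config and rejects bad input", {
  X <- matrix(rpois(48, 2), 6, 8)
  f1 <- factorize(X, nmf_config(rank = 2L, max_iter = 50L, seed = 5L))
  f2 <- factorize(X, nmf_config(rank = 2L, max_iter = 50L, seed = 5L))
  expect_identical(f1$W, f2$W)
  expect_identical(f1$objective_trace, f2$objective_trace)
  expect_error(factorize(matrix(0, 4, 4), nmf_config(rank = 2L)),
               class = "ns_degenerate_error")
  expect_error(factorize(matrix(-1, 4, 4), nmf_config(rank = 2L)),
               class = "ns_validation_error")
  expect_error(factorize(X, nmf_config(rank = 6L)),
               class = "ns_config_error")
})

test_that("rss matches the elementwise loop oracle", {
  expect_equal(rss(matrix(c(1, 0), 1), matrix(1), matrix(c(0, 1), 1)), 2)
  set.seed(21)
  X <- matrix(runif(12), 3, 4)
  W <- matrix(runif(6), 3, 2); H <- matrix(runif(8), 2, 4)
  expect_equal(rss(X, W, H), oracle_rss(X, W, H), tolerance = 1e-12)
  expect_equal(rss(W %*% H, W, H), 0)
})

test_that("cluster and basis assignment take the argmax with first-index ties", {
  H <- cbind(c(0.1, 0.9, 0.3), c(0.5, 0.5, 0.0), c(0, 0, 1))
  expect_equal(unname(assign_sample_clusters(H)), c(2L, 1L, 3L))
  W <- rbind(c(0.2, 0.7, 0.1), c(0.3, 0.3, 0.3))
  expect_equal(unname(assign_feature_basis(W)), c(2L, 1L))
  # loop oracle on random matrices
  set.seed(13)
  Hr <- matrix(runif(5 * 20), 5)
  expect_equal(unname(assign_sample_clusters(Hr)),
               vapply(seq_len(ncol(Hr)), function(j) {
                 best <- 1L
                 for (a in seq_len(nrow(Hr)))
                   if (Hr[a, j] > Hr[best, j]) best <- a
                 best
               }, integer(1)))
})

test_that("consensus matrices average run connectivities", {
  # hand average of two clusterings {a,b|c} and {a|b,c}
  C <- (oracle_connectivity(c(1, 1, 2)) + oracle_connectivity(c(1, 2, 2))) / 2
  expect_equal(C[1, 2], 0.5)
  expect_equal(C[2, 3], 0.5)
  expect_equal(C[1, 3], 0)
  expect_true(isSymmetric(C) && all(diag(C) == 1))

  # crisp blocks: every restart clusters identically -> entries in {0, 1}
  X <- planted_block_matrix(1, sigma = 0.05, n_feat = c(4, 4, 4), n_samp = 8)
  cm <- consensus_matrix(X, rank = 3, n_runs = 5,
                         cfg = nmf_config(rank = 3, max_iter = 200L),
                         seed = 2)
  expect_true(all(cm %in% c(0, 1)))
  expect_true(isSymmetric(unname(cm)))
  expect_true(all(diag(cm) == 1))
  expect_error(consensus_matrix(X, 3, n_runs = 1), class = "ns_config_error")
})

test_that("cophenetic coefficient matches a hand-built average-linkage case", {
  # perfect block structure is already ultrametric
  C <- oracle_connectivity(c(1, 1, 2, 2))
  expect_equal(cophenetic_coefficient(C), 1)
  # constant dissimilarity -> defined as 1
  expect_equal(cophenetic_coefficient(matrix(1, 3, 3)), 1)

  # 4 points, hand linkage: merge (1,2)@0.1, (3,4)@0.2, all@0.85
  d <- c(0.1, 0.8, 0.9, 1.0, 0.7, 0.2)  # pairs 12,13,14,23,24,34
  C <- diag(4)
  C[lower.tri(C)] <- 1 - d
  C <- C + t(C) - diag(diag(C))
  coph <- c(0.1, 0.85, 0.85, 0.85, 0.85, 0.2)
  expect_equal(cophenetic_coefficient(C), oracle_pearson(d, coph),
               tolerance = 1e-12)
  expect_error(cophenetic_coefficient(matrix(c(1, 0.5, 0, 1), 2)),
               class = "ns_validation_error")
})

test_that("rank-selection rules follow their curve arithmetic", {
  expect_equal(rank_from_cophenetic(c(1.0, 1.0, 0.9, 0.8), 2:5), 3L)
  expect_equal(rank_from_cophenetic(c(1.0, 0.9, 0.8, 0.7), 2:5), 2L)
  expect_true(is.na(rank_from_cophenetic(c(0.7, 0.8, 0.9, 1.0), 2:5)))
  # concave-then-convex RSS: second difference changes sign at rank 4
  expect_equal(rank_from_rss(c(20, 15, 5, 4.5, 4.4), 2:6), 4L)
  expect_true(is.na(rank_from_rss(c(20, 10, 5, 3, 2), 2:6)))
  expect_true(is.na(rank_from_rss(c(20, 10, 5), 2:4)))
})

test_that("the rank survey recovers planted block structure", {
  X <- planted_block_matrix(7)
  survey <- select_rank(X, 2:5, nmf_config(tol = 1e-4, max_iter = 300L),
                        n_runs = 10, seed = 7)
  expect_equal(survey$selected, 3L)
  expect_true(all(survey$cophenetic >= 0 & survey$cophenetic <= 1))
  expect_true(all(vapply(survey$consensus, function(C)
    isSymmetric(unname(C)) && all(diag(C) == 1), logical(1))))
  expect_error(select_rank(X, 1:3), class = "ns_config_error")
})
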