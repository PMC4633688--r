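test_that("distance similarity normalizes by the maximal pairwise squared distance", {
  W <- rbind(a = c(0, 0), b = c(1, 0), c = c(3, 0))
  s <- sim_dist_matrix(W)
  expect_equal(attr(s, "max_d"), 9)
  expect_equal(s["a", "b"], 1 - 1 / 9)
  expect_equal(s["a", "c"], 0)       # the MaxD pair
  expect_equal(diag(s), c(a = 1, b = 1, c = 1))
  # loop-oracle agreement on random instances
  set.seed(31)
  for (k in 1:5) {
    Wr <- matrix(runif(24), 6, 4)
    expect_equal(unname(sim_dist_matrix(Wr)), oracle_sim_dist(Wr),
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
  expect_error(sim_dist_matrix(rbind(c(1, 1), c(1, 1))),
               class = "ns_degenerate_error")
})

test_that("correlation similarity is row-wise Pearson with own-mean centering", {
  W <- rbind(a = c(1, 2, 3), b = c(2, 4, 6), c = c(3, 2, 1))
  s <- sim_corr_matrix(W)
  expect_equal(s["a", "b"], 1)        # proportional rows
  expect_equal(s["a", "c"], -1)       # reversal
  # oracle-computed value for (1,0,2) vs (0,1,1): centered vectors are
  # orthogonal, so the correlation is exactly 0
  W2 <- rbind(c(1, 0, 2), c(0, 1, 1))
  expect_equal(sim_corr_matrix(W2)[1, 2], oracle_pearson(c(1, 0, 2), c(0, 1, 1)))
  expect_equal(sim_corr_matrix(W2)[1, 2], 0)
  set.seed(32)
  Wr <- matrix(runif(24), 6, 4)
  expect_equal(unname(sim_corr_matrix(Wr)), oracle_sim_corr(Wr),
               tolerance = 1e-12)
  # constant row flagged
  expect_warning(sc <- sim_corr_matrix(rbind(c(1, 1, 1), c(0, 1, 2))),
                 "constant")
  expect_true(is.na(sc[1, 2]))
})

test_that("combined similarity is the elementwise mean", {
  expect_equal(combined_similarity(matrix(1), matrix(1)), matrix(1))
  expect_equal(combined_similarity(matrix(0.9672), matrix(1))[1, 1], 0.9836)
  expect_equal(combined_similarity(matrix(0.5), matrix(-0.5))[1, 1], 0)
  set.seed(33)
  Wr <- matrix(runif(24), 6, 4)
  sims <- similarity_matrices(Wr)
  expect_equal(sims$smx, (sims$sim_dist + sims$sim_corr) / 2,
               ignore_attr = TRUE)
  expect_true(isSymmetric(unname(sims$smx)))
  expect_true(all(sims$sim_dist >= 0 & sims$sim_dist <= 1))
  expect_true(all(sims$sim_corr >= -1 & sims$sim_corr <= 1 + 1e-12))
  expect_equal(unname(diag(sims$smx)), rep(1, 6))
})

test_that("redundant groups are same-basis connected components over the dual rule", {
  # chain a-b, b-c above theta in one basis -> single group {a,b,c}
  W <- rbind(a = c(10, 0.1), b = c(10.02, 0.1), c = c(10.04, 0.1),
             d = c(5, 0.1), e = c(0.1, 8))
  sims <- similarity_matrices(W)
  basis <- assign_feature_basis(W)
  grp <- find_redundant_groups(sims, basis, theta = 0.95)
  expect_length(grp$groups, 1L)
  expect_setequal(grp$groups[[1]]$members, c("a", "b", "c"))
  expect_equal(grp$groups[[1]]$basis, 1)
  # no pair above a near-one threshold -> empty
  expect_length(find_redundant_groups(sims, basis, theta = 0.999999)$groups, 0L)
  # brute-force grouping oracle on noisy duplicated rows
  set.seed(34)
  for (k in 1:5) {
    base <- matrix(runif(10 * 3, 0.2, 2), 10)
    Wn <- rbind(base, base[1, ] * (1 + rnorm(3, 0, 0.01)),
                base[1, ] * (1 + rnorm(3, 0, 0.01)))
    rownames(Wn) <- paste0("f", seq_len(nrow(Wn)))
    s <- similarity_matrices(Wn)
    b <- assign_feature_basis(Wn)
    got <- lapply(find_redundant_groups(s, b, 0.95)$groups, `[[`, "members")
    want <- lapply(oracle_groups(s$sim_dist, s$sim_corr, b, 0.95),
                   function(idx) rownames(Wn)[idx])
    expect_setequal(vapply(got, function(g) paste(sort(g), collapse = ","),
                           character(1)),
                    vapply(want, function(g) paste(sort(g), collapse = ","),
                           character(1)))
  }
})

test_that("raising theta never merges groups nor adds members", {
  set.seed(35)
  W <- matrix(runif(20 * 3, 0.1, 2), 20)
  W <- rbind(W, W[3, ] * 1.005, W[8, ] * 0.995)
  rownames(W) <- paste0("f", seq_len(nrow(W)))
  sims <- similarity_matrices(W)
  basis <- assign_feature_basis(W)
  thetas <- c(0.8, 0.9, 0.95, 0.99)
  groups <- lapply(thetas, function(t)
    lapply(find_redundant_groups(sims, basis, t)$groups, `[[`, "members"))
  for (i in seq_len(length(thetas) - 1)) {
    hi <- groups[[i + 1]]; lo <- groups[[i]]
    for (g in hi)
      expect_true(any(vapply(lo, function(G) all(g %in% G), logical(1))))
  }
})

test_that("planted copy-groups are recovered from the factorized basis", {
  # identifiable world: per basis one base feature and one copy-group at
  # well-separated magnitudes; copies carry 2% flip noise
  prs <- t(vapply(1:10, function(seed) {
    fx <- planted_redundancy_fixture(seed)
    fit <- factorize(fx$X, nmf_config(rank = 3, seed = 700 + seed))
    sims <- similarity_matrices(fit$W)
    grp <- find_redundant_groups(sims, assign_feature_basis(fit$W), 0.95)
    pairwise_prec_rec(lapply(grp$groups, `[[`, "members"), fx$planted)
  }, numeric(2)))
  expect_gte(mean(prs[, "precision"]), 0.9)
  expect_gte(mean(prs[, "recall"]), 0.9)
})

test_that("exact duplicates reach similarity ~1 through the factorization", {
  fx <- planted_redundancy_fixture(99, eps = 0)
  fit <- factorize(fx$X, nmf_config(rank = 3, seed = 123))
  sims <- similarity_matrices(fit$W)
  for (g in fx$planted) {
    cmb <- utils::combn(g, 2)
    for (k in seq_len(ncol(cmb))) {
      expect_gte(sims$sim_dist[cmb[1, k], cmb[2, k]], 0.999)
      expect_gte(sims$sim_corr[cmb[1, k], cmb[2, k]], 0.999)
    }
  }
})

test_that("mixed features follow the chosen strategy", {
  X <- cbind(A = c(0, 2, 4), B = c(2, 0, 4), C = c(1, 1, 1))
  m <- build_mixed_feature(X, c("A", "B"), "mean")
  expect_equal(m$values, c(1, 1, 4))
  r <- build_mixed_feature(X, c("A", "B"), "representative", seed = 4)
  expect_true(r$chosen %in% c("A", "B"))
  expect_equal(r$values, unname(X[, r$chosen]))
  # mean of 3 columns vs loop oracle
  set.seed(36)
  X3 <- matrix(runif(15), 5); colnames(X3) <- c("a", "b", "c")
  m3 <- build_mixed_feature(X3, c("a", "b", "c"), "mean")
  expect_equal(m3$values,
               vapply(1:5, function(i) sum(X3[i, ]) / 3, numeric(1)))
  expect_error(build_mixed_feature(X, c("A", "B"), "median"),
               class = "ns_config_error")
  expect_error(build_mixed_feature(X, "A"), class = "ns_validation_error")
})

test_that("subset assembly keeps non-grouped columns and appends mixed features", {
  gen <- generate_clinical(synthetic_spec(n_per_stage = c(10L, 12L, 11L),
                                          n_informative = 5L,
                                          n_irrelevant = 0L,
                                          group_sizes = c(2L), seed = 8L))
  ds <- gen$dataset
  # craft groups object directly
  g1 <- gen$truth$groups[[1]]
  groups <- structure(list(groups = list(list(members = g1, basis = 2L,
                                              mean_sim_dist = 0.99,
                                              mean_sim_corr = 0.99)),
                           theta = 0.95, rule = "dual", same_basis = TRUE),
                      class = "redundancy_groups")
  subset <- assemble_subset(ds, groups, "mean")
  expect_equal(length(subset$feature_ids), n_symptoms(ds) - 2 + 1)
  expect_identical(subset$kept, setdiff(colnames(ds$values), g1))
  expect_equal(subset$mixed[[1]]$id, "M21")
  expect_equal(unname(subset$values[, "M21"]),
               unname(rowMeans(ds$values[, g1])))
  expect_true(all(subset$values >= 0))
  # apply_subset reproduces the training transformation on the same data
  expect_equal(apply_subset(subset, ds), subset$values)

  # empty groups -> identity transformation
  empty <- structure(list(groups = list(), theta = 0.95, rule = "dual",
                          same_basis = TRUE), class = "redundancy_groups")
  ident <- assemble_subset(ds, empty)
  expect_equal(ident$values, ds$values, ignore_attr = TRUE)

  # overlapping groups -> validation error
  overlap <- groups
  overlap$groups[[2]] <- list(members = c(g1[1], subset$kept[1]),
                              basis = 2L, mean_sim_dist = 1, mean_sim_corr = 1)
  expect_error(assemble_subset(ds, overlap), class = "ns_validation_error")
})

test_that("the counting identity kept + mixed = n - sum(sizes) + #groups holds", {
  # the tabulated configuration: 49 features, groups of sizes 3,2,2,5,2,2
  sizes <- c(3L, 2L, 2L, 5L, 2L, 2L)
  ids <- paste0("V", 1:49)
  values <- matrix(1L, 4, 49, dimnames = list(NULL, ids))
  values[1, ] <- 0L  # avoid constant columns
  ds <- clinical_dataset(values, stage = c(1L, 1L, 2L, 3L))
  start <- 1L
  glist <- list()
  for (i in seq_along(sizes)) {
    glist[[i]] <- list(members = ids[start:(start + sizes[i] - 1L)],
                       basis = ((i - 1L) %/% 2L) + 1L,
                       mean_sim_dist = 0.96, mean_sim_corr = 0.99)
    start <- start + sizes[i]
  }
  groups <- structure(list(groups = glist, theta = 0.95, rule = "dual",
                           same_basis = TRUE), class = "redundancy_groups")
  subset <- assemble_subset(ds, groups)
  expect_equal(length(subset$kept), 33L)
  expect_equal(length(subset$mixed), 6L)
  expect_equal(length(subset$feature_ids), 39L)
  expect_identical(vapply(subset$mixed, `[[`, character(1), "id"),
                   c("M11", "M12", "M21", "M22", "M31", "M32"))
})
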