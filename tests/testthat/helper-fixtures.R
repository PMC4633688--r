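# Shared fixtures and independent brute-force oracles. Oracles are written
# as plain loops over definitions and must stay independent of the package
# code paths they check.

# --- tiny clinical dataset ---------------------------------------------------

toy_dataset <- function() {
  values <- rbind(c(0L, 2L, 1L),
                  c(1L, 0L, 1L),
                  c(0L, 1L, 0L),
                  c(2L, 3L, 0L))
  clinical_dataset(values,
                   symptom_ids = c("V1", "V2", "V3"),
                   sample_ids = c("a", "b", "c", "d"),
                   substage = c("IA", "IIB", "IIA", "IIIB"))
}

# --- brute-force oracles -----------------------------------------------------

oracle_kl <- function(X, W, H) {
  WH <- matrix(0, nrow(X), ncol(X))
  for (i in seq_len(nrow(X)))
    for (j in seq_len(ncol(X)))
      for (a in seq_len(ncol(W)))
        WH[i, j] <- WH[i, j] + W[i, a] * H[a, j]
  total <- 0
  for (i in seq_len(nrow(X)))
    for (j in seq_len(ncol(X))) {
      if (X[i, j] > 0) {
        if (WH[i, j] == 0) return(Inf)
        total <- total + X[i, j] * log(X[i, j] / WH[i, j])
      }
      total <- total - X[i, j] + WH[i, j]
    }
  total
}

oracle_rss <- function(X, W, H) {
  total <- 0
  for (i in seq_len(nrow(X)))
    for (j in seq_len(ncol(X))) {
      pred <- sum(W[i, ] * H[, j])
      total <- total + (X[i, j] - pred)^2
    }
  total
}

oracle_sim_dist <- function(W) {
  n <- nrow(W)
  d2 <- matrix(0, n, n)
  for (i in seq_len(n))
    for (j in seq_len(n))
      d2[i, j] <- sum((W[i, ] - W[j, ])^2)
  1 - d2 / max(d2)
}

oracle_pearson <- function(x, y) {
  xm <- sum(x) / length(x); ym <- sum(y) / length(y)
  num <- sum((x - xm) * (y - ym))
  num / sqrt(sum((x - xm)^2) * sum((y - ym)^2))
}

oracle_sim_corr <- function(W) {
  n <- nrow(W)
  s <- diag(n)
  for (i in seq_len(n))
    for (j in seq_len(n))
      if (i != j) s[i, j] <- oracle_pearson(W[i, ], W[j, ])
  s
}

oracle_connectivity <- function(clusters) {
  n <- length(clusters)
  C <- matrix(0, n, n)
  for (i in seq_len(n))
    for (j in seq_len(n))
      if (clusters[i] == clusters[j]) C[i, j] <- 1
  C
}

# all-pairs threshold grouping by explicit transitive closure
oracle_groups <- function(sim_dist, sim_corr, basis, theta) {
  n <- nrow(sim_dist)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n))
    for (j in seq_len(n))
      if (i != j && sim_dist[i, j] >= theta && sim_corr[i, j] >= theta &&
          basis[i] == basis[j])
        adj[i, j] <- TRUE
  reach <- adj | diag(n) > 0
  for (k in seq_len(n))
    for (i in seq_len(n))
      for (j in seq_len(n))
        if (reach[i, k] && reach[k, j]) reach[i, j] <- TRUE
  comp <- rep(NA_integer_, n)
  nc <- 0L
  for (i in seq_len(n)) if (is.na(comp[i])) {
    nc <- nc + 1L
    comp[which(reach[i, ])] <- nc
  }
  groups <- list()
  for (k in seq_len(nc)) {
    members <- which(comp == k)
    if (length(members) >= 2) groups[[length(groups) + 1L]] <- members
  }
  groups
}

# --- pairwise precision / recall against planted groups ---------------------

group_pairs <- function(groups) {
  out <- character(0)
  for (g in groups)
    if (length(g) >= 2) {
      cmb <- utils::combn(sort(g), 2)
      out <- c(out, paste(cmb[1, ], cmb[2, ]))
    }
  out
}

pairwise_prec_rec <- function(found, planted) {
  fp <- group_pairs(found); pp <- group_pairs(planted)
  c(precision = if (length(fp)) mean(fp %in% pp) else 1,
    recall = if (length(pp)) mean(pp %in% fp) else 1)
}

# --- planted-structure fixtures ---------------------------------------------

# 3 sample blocks x 3 feature blocks, elevated on the diagonal; clipped
# Gaussian noise keeps the blocks separable
planted_block_matrix <- function(seed, sigma = 0.3, n_feat = c(16, 17, 16),
                                 n_samp = 40) {
  set.seed(seed)
  fb <- rep(1:3, n_feat)
  sb <- rep(1:3, each = n_samp)
  B <- matrix(0.1, sum(n_feat), 3 * n_samp)
  for (k in 1:3) B[fb == k, sb == k] <- 2
  pmax(B + matrix(stats::rnorm(length(B), 0, sigma), nrow(B)), 0)
}

# Minimal identifiable redundancy fixture: per basis one base feature
# (Poisson rate 0.5) and one copy-group source (rate 3.0); copy columns
# get symmetric flip noise. The magnitude ratio keeps every non-copy pair
# outside the theta = 0.95 distance ball of the basis-row similarity (the
# measure supports only ~2 magnitude levels per basis; see the vignette).
planted_redundancy_fixture <- function(seed, eps = 0.02, n_samp = 40) {
  profiles <- rbind(
    c(0.5, 0.05, 0.02), c(3.0, 0.10, 0.05),
    c(0.05, 0.5, 0.02), c(0.10, 3.0, 0.05),
    c(0.05, 0.02, 0.5), c(0.10, 0.05, 3.0))
  set.seed(seed)
  blocks <- rep(1:3, each = n_samp)
  X <- matrix(stats::rpois(6 * 3 * n_samp, profiles[, blocks]), 6)
  rownames(X) <- paste0("F", 1:6)
  copies <- c(F2 = 2L, F4 = 1L, F6 = 1L)
  planted <- list()
  for (src in names(copies)) {
    members <- src
    for (k in seq_len(copies[[src]])) {
      col <- X[src, ]
      flip <- stats::runif(ncol(X)) < eps
      col[flip] <- pmax(0L, col[flip] +
                          sample(c(-1L, 1L), sum(flip), replace = TRUE))
      X <- rbind(X, col)
      id <- paste0(src, "c", k)
      rownames(X)[nrow(X)] <- id
      members <- c(members, id)
    }
    planted[[length(planted) + 1L]] <- members
  }
  list(X = X, planted = planted)
}

# screening world with the spec's margins: irrelevant < 0.05 everywhere,
# informative peak >= 0.2 in at least one stage
screening_world <- function(seed, p_per_stage = c(134, 133, 133),
                            n_informative = 20, n_irrelevant = 6) {
  set.seed(seed)
  stage <- rep(1:3, p_per_stage)
  p <- length(stage)
  cols <- list(); flag <- logical(0)
  for (k in seq_len(n_informative)) {
    probs <- stats::runif(3, 0.01, 0.08)
    probs[sample(3, 1)] <- stats::runif(1, 0.2, 0.8)
    cols[[length(cols) + 1L]] <- as.integer(stats::runif(p) < probs[stage])
    flag <- c(flag, FALSE)
  }
  for (k in seq_len(n_irrelevant)) {
    probs <- stats::runif(3, 0.005, 0.045)
    cols[[length(cols) + 1L]] <- as.integer(stats::runif(p) < probs[stage])
    flag <- c(flag, TRUE)
  }
  values <- do.call(cbind, cols)
  colnames(values) <- paste0("V", seq_along(cols))
  ds <- clinical_dataset(values, stage = stage)
  list(dataset = ds, irrelevant = colnames(values)[flag])
}

# separable three-blob fixture for LS-SVM tests
blob_data <- function(seed, n_per_class = 20, spread = 0.3, gap = 4) {
  set.seed(seed)
  centers <- rbind(c(0, 0), c(gap, 0), c(0, gap))
  X <- NULL; y <- integer(0)
  for (cl in 1:3) {
    X <- rbind(X, sweep(matrix(stats::rnorm(2 * n_per_class, 0, spread),
                               ncol = 2), 2, centers[cl, ], "+"))
    y <- c(y, rep(cl, n_per_class))
  }
  list(X = X, y = y)
}
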