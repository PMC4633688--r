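#' NMF configuration
#'
#' Settings for regularized Kullback-Leibler NMF. The objective is
#' `D_KL(X, WH) + lambda_w * F1(W) + lambda_h * F2(H)` with a Tikhonov
#' smoothness penalty `F1(W) = 1/2 * sum((W - c)^2)` pulling every basis
#' entry towards the constant `c`, and a sparsity term
#' `F2(H) = 1/2 * sum over rows h of H of (||h||_2^2 - alpha^2 ||h||_1^2)`.
#' With the default `lambda_w = lambda_h = 0` the factorization is plain
#' Lee-Seung KL NMF, for which the multiplicative updates provably never
#' increase the objective.
#'
#' @param rank factorization rank r (>= 2); must satisfy r < min(dim(X)).
#' @param c smoothness target constant (>= 0).
#' @param alpha sparsity weight inside F2 (>= 0). Note the F2 form rewards
#'   rather than penalizes L1 mass once `alpha > 1`; values in `[0, 1]`
#'   are the sensible range.
#' @param lambda_w,lambda_h nonnegative weights on F1, F2.
#' @param max_iter iteration cap (default 2000).
#' @param tol relative objective-change stopping tolerance (default 1e-6).
#' @param seed RNG seed for the random initialization.
#' @return an `nmf_config` list.
#' @export
nmf_config <- function(rank = 3L, c = 0, alpha = 0, lambda_w = 0,
                       lambda_h = 0, max_iter = 2000L, tol = 1e-6,
                       seed = 1L) {
  rank <- as.integer(rank)
  if (rank < 2L) ns_abort("`rank` must be >= 2", "ns_config_error")
  if (c < 0 || alpha < 0 || lambda_w < 0 || lambda_h < 0)
    ns_abort("regularization parameters must be nonnegative",
             "ns_config_error")
  if (!(tol > 0)) ns_abort("`tol` must be positive", "ns_config_error")
  max_iter <- as.integer(max_iter)
  if (max_iter < 1L) ns_abort("`max_iter` must be >= 1", "ns_config_error")
  structure(list(rank = rank, c = c, alpha = alpha, lambda_w = lambda_w,
                 lambda_h = lambda_h, max_iter = max_iter, tol = tol,
                 seed = as.integer(seed)),
            class = "nmf_config")
}

#' Kullback-Leibler divergence between a matrix and its factorization
#'
#' `D = sum_ij [ X_ij log(X_ij / (WH)_ij) - X_ij + (WH)_ij ]` with the
#' convention `0 log 0 = 0`. Where `(WH)_ij = 0` but `X_ij > 0` the
#' divergence is infinite and `Inf` is returned.
#'
#' @param X nonnegative matrix (features x samples).
#' @param W,H factor matrices with conformable shapes.
#' @return scalar >= 0 (possibly `Inf`).
#' @export
kl_divergence <- function(X, W, H) {
  WH <- W %*% H
  pos <- X > 0
  if (any(WH[pos] == 0)) return(Inf)
  sum(X[pos] * log(X[pos] / WH[pos])) - sum(X) + sum(WH)
}

#' Regularization penalty values
#'
#' @param W,H factor matrices.
#' @param c,alpha see [nmf_config()].
#' @return named vector `c(F1 = , F2 = )`.
#' @export
regularization_value <- function(W, H, c = 0, alpha = 0) {
  F1 <- 0.5 * sum((W - c)^2)
  F2 <- 0.5 * sum(rowSums(H^2) - alpha^2 * rowSums(abs(H))^2)
  c(F1 = F1, F2 = F2)
}

#' Residual sum of squares of a factorization
#'
#' @param X data matrix.
#' @param W,H factor matrices.
#' @return `sum((X - WH)^2)`.
#' @export
rss <- function(X, W, H) {
  sum((X - W %*% H)^2)
}

#' Factorize a nonnegative matrix by multiplicative KL updates
#'
#' Runs Lee-Seung multiplicative updates for the KL objective from a
#' seeded uniform-random initialization scaled so `mean(WH) = mean(X)`.
#' When `lambda_w`/`lambda_h` are nonzero the updates carry
#' gradient-derived multiplicative corrections (positive gradient parts in
#' the denominator, negative parts in the numerator, floored at 1e-12);
#' this is a heuristic extension, and the monotonic-descent guarantee is
#' only asserted for the unregularized case.
#'
#' @param X nonnegative matrix, features in rows, samples in columns.
#' @param cfg an [nmf_config()].
#' @return an `nmf_fit`: list with `W` (features x rank), `H` (rank x
#'   samples), `objective_trace` (per-iteration total objective),
#'   `converged`, `iterations`, `config`.
#' @export
factorize <- function(X, cfg = nmf_config()) {
  stopifnot(inherits(cfg, "nmf_config"))
  X <- as.matrix(X)
  if (any(X < 0))
    ns_abort("X has negative entries", "ns_validation_error")
  if (all(X == 0))
    ns_abort("X is identically zero", "ns_degenerate_error")
  n <- nrow(X); p <- ncol(X); r <- cfg$rank
  if (r >= min(n, p))
    ns_abort("rank must be smaller than both dimensions of X",
             "ns_config_error")
  eps <- 1e-12
  init <- ns_with_seed(cfg$seed, {
    W <- matrix(stats::runif(n * r), n, r)
    H <- matrix(stats::runif(r * p), r, p)
    list(W = W, H = H)
  })
  W <- init$W; H <- init$H
  s <- mean(X) / mean(W %*% H)
  W <- W * sqrt(s); H <- H * sqrt(s)

  objective <- function(W, H) {
    d <- kl_divergence(X, W, H)
    if (cfg$lambda_w > 0 || cfg$lambda_h > 0) {
      reg <- regularization_value(W, H, cfg$c, cfg$alpha)
      d <- d + cfg$lambda_w * reg[["F1"]] + cfg$lambda_h * reg[["F2"]]
    }
    d
  }

  trace <- numeric(cfg$max_iter)
  converged <- FALSE
  prev <- NA_real_
  tH <- t(H)
  for (it in seq_len(cfg$max_iter)) {
    ratio <- X / (W %*% H + eps)
    numW <- ratio %*% tH
    denW <- matrix(rowSums(H), n, r, byrow = TRUE) + eps
    if (cfg$lambda_w > 0) {
      numW <- numW + cfg$lambda_w * cfg$c
      denW <- denW + cfg$lambda_w * W
    }
    W <- pmax(W * numW / denW, eps)

    ratio <- X / (W %*% H + eps)
    numH <- crossprod(W, ratio)
    denH <- matrix(colSums(W), r, p) + eps
    if (cfg$lambda_h > 0) {
      numH <- numH + cfg$lambda_h * cfg$alpha^2 * rowSums(abs(H))
      denH <- denH + cfg$lambda_h * H
    }
    H <- pmax(H * numH / denH, eps)
    tH <- t(H)

    obj <- objective(W, H)
    if (!is.finite(obj))
      ns_abort(sprintf("non-finite objective at iteration %d", it),
               "ns_numeric_error")
    trace[it] <- obj
    if (it > 1L && abs(prev - obj) <= cfg$tol * max(abs(prev), eps)) {
      converged <- TRUE
      trace <- trace[seq_len(it)]
      break
    }
    prev <- obj
  }
  if (!converged) trace <- trace[seq_len(cfg$max_iter)]
  rownames(W) <- rownames(X)
  colnames(H) <- colnames(X)
  colnames(W) <- rownames(H) <- paste0("B", seq_len(r))
  structure(list(W = W, H = H, objective_trace = trace,
                 converged = converged, iterations = length(trace),
                 config = cfg),
            class = "nmf_fit")
}

#' @export
print.nmf_fit <- function(x, ...) {
  cat(sprintf("<nmf_fit> rank %d, %d x %d, %d iterations (%s), objective %.6g\n",
              x$config$rank, nrow(x$W), ncol(x$H), x$iterations,
              if (x$converged) "converged" else "max_iter",
              utils::tail(x$objective_trace, 1)))
  invisible(x)
}

#' Cluster samples by the dominant basis of H
#'
#' Sample j is placed in cluster k when `H[k, j]` is the largest entry of
#' its column; ties break to the smallest index.
#'
#' @param H nonnegative coefficient matrix (rank x samples).
#' @return integer cluster index per sample.
#' @export
assign_sample_clusters <- function(H) {
  stopifnot(all(H >= 0))
  stats::setNames(apply(H, 2L, which.max), colnames(H))
}

#' Relate each feature to its dominant basis
#'
#' Feature i relates to basis j when `W[i, j]` is the largest entry of its
#' row; ties break to the smallest index.
#'
#' @param W nonnegative basis matrix (features x rank).
#' @return integer basis index per feature.
#' @export
assign_feature_basis <- function(W) {
  stopifnot(all(W >= 0))
  stats::setNames(apply(W, 1L, which.max), rownames(W))
}

connectivity_matrix <- function(clusters) {
  (outer(clusters, clusters, "==")) * 1
}

# Multi-restart engine shared by consensus_matrix() and select_rank():
# runs n_runs seeded factorizations at one rank, accumulating the sample
# connectivity consensus and keeping the best-objective fit.
nmf_restarts <- function(X, rank, n_runs, cfg, seed) {
  run_seeds <- ns_derive_seeds(seed, n_runs)
  p <- ncol(X)
  consensus <- matrix(0, p, p)
  best <- NULL
  objectives <- numeric(n_runs)
  for (k in seq_len(n_runs)) {
    cfg_k <- cfg
    cfg_k$rank <- as.integer(rank)
    cfg_k$seed <- run_seeds[k]
    fit <- factorize(X, cfg_k)
    objectives[k] <- utils::tail(fit$objective_trace, 1)
    consensus <- consensus + connectivity_matrix(assign_sample_clusters(fit$H))
    if (is.null(best) || objectives[k] < utils::tail(best$objective_trace, 1))
      best <- fit
  }
  consensus <- consensus / n_runs
  dimnames(consensus) <- list(colnames(X), colnames(X))
  list(consensus = consensus, best = best, objectives = objectives)
}

#' Consensus matrix over NMF restarts
#'
#' Averages, over `n_runs` random restarts, the sample connectivity
#' matrices induced by [assign_sample_clusters()]: entry (j, k) is the
#' fraction of runs in which samples j and k fell in the same cluster.
#'
#' @param X nonnegative matrix (features x samples).
#' @param rank factorization rank.
#' @param n_runs number of restarts (>= 2; default 30).
#' @param cfg an [nmf_config()] supplying the update settings.
#' @param seed seed from which per-run seeds are derived.
#' @return symmetric p x p matrix with unit diagonal, entries in [0, 1].
#' @export
consensus_matrix <- function(X, rank, n_runs = 30L, cfg = nmf_config(rank),
                             seed = cfg$seed) {
  if (n_runs < 2L) ns_abort("`n_runs` must be >= 2", "ns_config_error")
  nmf_restarts(X, rank, n_runs, cfg, seed)$consensus
}

#' Cophenetic correlation of a consensus matrix
#'
#' Pearson correlation between the off-diagonal consensus dissimilarities
#' `1 - C` and the cophenetic distances of the average-linkage dendrogram
#' built on them. A value near 1 means the clustering is stable across
#' restarts. Constant dissimilarities are defined to give 1 (perfectly
#' reproducible clustering); negative correlations are clipped to 0 so the
#' reported coefficient lies in [0, 1].
#'
#' @param consensus symmetric matrix with unit diagonal.
#' @return scalar in [0, 1].
#' @export
cophenetic_coefficient <- function(consensus) {
  if (!isSymmetric(unname(consensus), tol = 1e-8))
    ns_abort("consensus matrix must be symmetric", "ns_validation_error")
  d <- stats::as.dist(1 - consensus)
  if (length(d) < 1L) return(1)
  if (stats::sd(d) == 0) return(1)
  hc <- stats::hclust(d, method = "average")
  cd <- stats::cophenetic(hc)
  if (stats::sd(cd) == 0) return(1)
  max(0, stats::cor(as.vector(d), as.vector(cd)))
}

#' Rank-selection rule on a cophenetic curve
#'
#' The chosen rank is the smallest r in the examined range for which the
#' cophenetic coefficient at r + 1 falls below the one at r (the rank at
#' which stability starts decreasing).
#'
#' @param coph cophenetic coefficients, one per rank.
#' @param ranks the examined ranks, same length, ascending.
#' @return the selected rank, or `NA` when the curve never decreases.
#' @export
rank_from_cophenetic <- function(coph, ranks) {
  stopifnot(length(coph) == length(ranks))
  drop <- which(diff(coph) < 0)
  if (!length(drop)) return(NA_integer_)
  as.integer(ranks[min(drop)])
}

#' Rank-selection rule on an RSS curve
#'
#' Operationalizes the inflection-point rule as the first interior rank at
#' which the discrete second difference of the RSS curve changes sign.
#'
#' @param rss_values residual sums of squares, one per rank.
#' @param ranks the examined ranks, same length, ascending.
#' @return the selected rank, or `NA` when no sign change occurs.
#' @export
rank_from_rss <- function(rss_values, ranks) {
  stopifnot(length(rss_values) == length(ranks))
  if (length(ranks) < 4L) return(NA_integer_)
  d2 <- diff(rss_values, differences = 2L)  # d2[i] belongs to ranks[i + 1]
  s <- sign(d2)
  change <- which(s[-1L] != s[-length(s)] & s[-1L] != 0)
  if (!length(change)) return(NA_integer_)
  as.integer(ranks[min(change) + 2L])
}

#' Survey factorization ranks by consensus stability and RSS
#'
#' For every rank in `rank_range` this runs `n_runs` restarts, records the
#' consensus matrix, its cophenetic coefficient, and the RSS of the
#' best-objective fit, then applies both selection rules. The cophenetic
#' rule decides the selected rank; when it is inconclusive (monotone
#' curve) the RSS rule is used, and when both fail the survey falls back
#' to the rank of maximal cophenetic coefficient, flagged `"inconclusive"`.
#'
#' @param X nonnegative matrix (features x samples).
#' @param rank_range integer ranks to examine (default 2:7).
#' @param cfg an [nmf_config()].
#' @param n_runs restarts per rank (default 30).
#' @param seed master seed for the survey.
#' @return a `rank_survey`: list with `ranks`, `cophenetic`, `rss`,
#'   `consensus` (list of matrices), `best_fits` (list of `nmf_fit`),
#'   `candidates` (per-rule answers), `selected`, `rule`.
#' @export
select_rank <- function(X, rank_range = 2:7, cfg = nmf_config(),
                        n_runs = 30L, seed = cfg$seed) {
  rank_range <- sort(as.integer(rank_range))
  if (min(rank_range) < 2L || max(rank_range) >= min(dim(X)))
    ns_abort("`rank_range` must lie within (1, min(dim(X)))",
             "ns_config_error")
  rank_seeds <- ns_derive_seeds(seed, length(rank_range))
  coph <- numeric(length(rank_range))
  rssv <- numeric(length(rank_range))
  consensus <- vector("list", length(rank_range))
  best_fits <- vector("list", length(rank_range))
  for (i in seq_along(rank_range)) {
    res <- nmf_restarts(X, rank_range[i], n_runs, cfg, rank_seeds[i])
    consensus[[i]] <- res$consensus
    best_fits[[i]] <- res$best
    coph[i] <- cophenetic_coefficient(res$consensus)
    rssv[i] <- rss(X, res$best$W, res$best$H)
  }
  cand_coph <- rank_from_cophenetic(coph, rank_range)
  cand_rss <- rank_from_rss(rssv, rank_range)
  if (!is.na(cand_coph)) {
    selected <- cand_coph; rule <- "cophenetic"
  } else if (!is.na(cand_rss)) {
    selected <- cand_rss; rule <- "rss"
  } else {
    selected <- rank_range[which.max(coph)]; rule <- "inconclusive"
  }
  names(consensus) <- names(best_fits) <- rank_range
  structure(list(ranks = rank_range, cophenetic = coph, rss = rssv,
                 consensus = consensus, best_fits = best_fits,
                 candidates = c(cophenetic = cand_coph, rss = cand_rss),
                 selected = selected, rule = rule),
            class = "rank_survey")
}

#' @export
print.rank_survey <- function(x, ...) {
  cat("<rank_survey>\n")
  print(data.frame(rank = x$ranks, cophenetic = round(x$cophenetic, 4),
                   rss = signif(x$rss, 6)), row.names = FALSE)
  cat(sprintf("selected rank: %s (rule: %s)\n", x$selected, x$rule))
  invisible(x)
}

#' Write per-rank diagnostics as TSV
#'
#' @param survey a [select_rank()] result.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_rank_survey <- function(survey, path) {
  utils::write.table(
    data.frame(rank = survey$ranks, cophenetic = survey$cophenetic,
               rss = survey$rss),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
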