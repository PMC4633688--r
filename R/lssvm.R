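#' Gaussian RBF kernel
#'
#' `K(x, y) = exp(-||x - y||^2 / sigma2)` (no factor 2 in the
#' denominator, the common LS-SVM parameterization).
#'
#' @param x,y numeric vectors of equal length.
#' @param sigma2 kernel width (> 0).
#' @return scalar in (0, 1].
#' @export
rbf_kernel <- function(x, y, sigma2) {
  if (!(sigma2 > 0)) ns_abort("`sigma2` must be positive", "ns_config_error")
  exp(-sum((x - y)^2) / sigma2)
}

# Cross squared-Euclidean distances between rows of A and rows of B.
cross_dist2 <- function(A, B = A) {
  a2 <- rowSums(A^2); b2 <- rowSums(B^2)
  d2 <- outer(a2, b2, "+") - 2 * A %*% t(B)
  pmax(d2, 0)
}

rbf_kernel_matrix <- function(A, B = A, sigma2) {
  exp(-cross_dist2(A, B) / sigma2)
}

#' Train a binary least-squares SVM
#'
#' Solves the LS-SVM dual KKT linear system
#' `[[0, y'], [y, Omega + I/gamma]] [b; alpha] = [0; 1]` with
#' `Omega_ij = y_i y_j K(x_i, x_j)`; the decision value is
#' `f(x) = sum_i alpha_i y_i K(x_i, x) + b` and the predicted label its
#' sign. Training is a single dense solve, so results are exactly
#' reproducible.
#'
#' @param X training inputs, samples in rows.
#' @param y labels in `{-1, +1}` (both present).
#' @param sigma2 RBF width (> 0).
#' @param gamma regularization (> 0); larger values fit the training data
#'   more tightly.
#' @return an `lssvm_binary` model: `X`, `y`, `alpha`, `b`, `sigma2`,
#'   `gamma`.
#' @export
lssvm_train <- function(X, y, sigma2, gamma) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (nrow(X) < 2L || !setequal(unique(y), c(-1, 1)))
    ns_abort("need >= 2 samples with both labels -1 and +1",
             "ns_validation_error")
  if (!(gamma > 0)) ns_abort("`gamma` must be positive", "ns_config_error")
  K <- rbf_kernel_matrix(X, X, sigma2)
  sol <- lssvm_solve_kernel(K, y, gamma)
  structure(list(X = X, y = y, alpha = sol$alpha, b = sol$b,
                 sigma2 = sigma2, gamma = gamma),
            class = "lssvm_binary")
}

# Core dual solve given a precomputed kernel submatrix.
lssvm_solve_kernel <- function(K, y, gamma) {
  m <- length(y)
  Omega <- (y %o% y) * K
  A <- rbind(c(0, y), cbind(y, Omega + diag(m) / gamma))
  rhs <- c(0, rep(1, m))
  sol <- tryCatch(solve(A, rhs), error = function(e)
    ns_abort(sprintf("singular KKT system (condition estimate %.3g)",
                     kappa(A)), "ns_numeric_error"))
  list(b = sol[1L], alpha = sol[-1L])
}

#' KKT residual of a trained binary machine
#'
#' Rebuilds the dual system and returns the infinity norm of its residual
#' at the stored solution; a correct solve gives essentially zero.
#'
#' @param model an `lssvm_binary`.
#' @return scalar residual.
#' @export
kkt_residual <- function(model) {
  stopifnot(inherits(model, "lssvm_binary"))
  K <- rbf_kernel_matrix(model$X, model$X, model$sigma2)
  m <- length(model$y)
  Omega <- (model$y %o% model$y) * K
  A <- rbind(c(0, model$y), cbind(model$y, Omega + diag(m) / model$gamma))
  rhs <- c(0, rep(1, m))
  max(abs(A %*% c(model$b, model$alpha) - rhs))
}

#' Decision values of a binary LS-SVM
#'
#' @param object an `lssvm_binary`.
#' @param newdata samples x features matrix.
#' @param ... unused.
#' @return numeric decision values; the predicted label is their sign.
#' @export
predict.lssvm_binary <- function(object, newdata, ...) {
  K <- rbf_kernel_matrix(as.matrix(newdata), object$X, object$sigma2)
  drop(K %*% (object$alpha * object$y) + object$b)
}

#' Train a one-vs-rest multiclass LS-SVM
#'
#' One binary machine per class (that class +1, the rest -1); prediction
#' is the argmax of the decision values, ties to the smallest class index.
#'
#' @param X training inputs, samples in rows.
#' @param labels integer class labels (>= 2 distinct values).
#' @param sigma2,gamma kernel width and regularization.
#' @return an `lssvm_multiclass` model.
#' @export
lssvm_multiclass <- function(X, labels, sigma2, gamma) {
  X <- as.matrix(X)
  classes <- sort(unique(labels))
  if (length(classes) < 2L)
    ns_abort("single-class data: multiclass training is degenerate",
             "ns_degenerate_error")
  machines <- lapply(classes, function(cl)
    lssvm_train(X, ifelse(labels == cl, 1, -1), sigma2, gamma))
  structure(list(classes = classes, machines = machines,
                 sigma2 = sigma2, gamma = gamma),
            class = "lssvm_multiclass")
}

#' Predict classes with a multiclass LS-SVM
#'
#' @param object an `lssvm_multiclass`.
#' @param newdata samples x features matrix.
#' @param ... unused.
#' @return predicted class labels.
#' @export
predict.lssvm_multiclass <- function(object, newdata, ...) {
  dec <- vapply(object$machines, predict, numeric(nrow(as.matrix(newdata))),
                newdata = newdata)
  dec <- matrix(dec, ncol = length(object$classes))
  object$classes[apply(dec, 1L, which.max)]
}

#' Deterministic stratified k-fold assignment
#'
#' Shuffles each class under `seed` and deals its samples to folds
#' round-robin, so every fold has near-equal class composition.
#'
#' @param labels class labels.
#' @param k number of folds (>= 2); every class must have >= k samples.
#' @param seed RNG seed.
#' @return integer fold index per sample.
#' @export
make_folds <- function(labels, k = 5L, seed = 1L) {
  k <- as.integer(k)
  if (k < 2L) ns_abort("`k` must be >= 2", "ns_config_error")
  tab <- table(labels)
  if (any(tab < k))
    ns_abort("a class has fewer samples than folds", "ns_strat_error")
  folds <- integer(length(labels))
  perm <- ns_with_seed(seed, {
    lapply(sort(unique(labels)), function(cl) sample(which(labels == cl)))
  })
  for (idx in perm)
    folds[idx] <- rep_len(seq_len(k), length(idx))
  folds
}

# Multiclass CV accuracy from a precomputed full kernel matrix; used by
# grid_search so the n x n distance matrix is exponentiated once per
# sigma2 rather than once per fold.
lssvm_cv_kernel <- function(K, labels, gamma, folds) {
  classes <- sort(unique(labels))
  vapply(sort(unique(folds)), function(f) {
    tr <- which(folds != f); te <- which(folds == f)
    dec <- vapply(classes, function(cl) {
      y <- ifelse(labels[tr] == cl, 1, -1)
      sol <- lssvm_solve_kernel(K[tr, tr, drop = FALSE], y, gamma)
      drop(K[te, tr, drop = FALSE] %*% (sol$alpha * y) + sol$b)
    }, numeric(length(te)))
    dec <- matrix(dec, ncol = length(classes))
    mean(classes[apply(dec, 1L, which.max)] == labels[te])
  }, numeric(1))
}

#' Default grid-search exponent levels
#'
#' `sigma2 = 10^a` over 24 levels (`a` from -1 in steps of 0.25) and
#' `gamma = 10^b` over 25 levels (`b` from -1 in steps of 0.2), i.e. 600
#' (sigma2, gamma) pairs. `full = TRUE` extends both ranges to their
#' stated endpoints (a up to 5, b up to 4), giving 25 x 26 levels.
#'
#' @param full include the final endpoint of each range.
#' @return list with numeric vectors `a` and `b`.
#' @export
default_grid <- function(full = FALSE) {
  a <- seq(-1, 5, by = 0.25)
  b <- seq(-1, 4, by = 0.2)
  if (!full) {
    a <- a[seq_len(24L)]
    b <- b[seq_len(25L)]
  }
  list(a = a, b = b)
}

#' Grid search for LS-SVM kernel parameters
#'
#' Evaluates stratified k-fold cross-validation accuracy of the one-vs-rest
#' LS-SVM for every `(sigma2, gamma) = (10^a, 10^b)` cell and reports the
#' best cell (maximum mean accuracy; ties to the smaller `a`, then the
#' smaller `b`).
#'
#' @param X samples x features matrix.
#' @param labels class labels; every class needs >= `folds` samples.
#' @param a_range,b_range exponent levels; default [default_grid()].
#' @param folds number of CV folds (default 5).
#' @param seed seed for the fold assignment.
#' @return a `grid_search_report`: data frame `grid` (a, b, sigma2, gamma,
#'   mean_acc, sd_acc), `best` row, `folds`, `seed`, `fold_assignment`.
#' @export
grid_search <- function(X, labels, a_range = default_grid()$a,
                        b_range = default_grid()$b, folds = 5L, seed = 1L) {
  X <- as.matrix(X)
  folds_idx <- make_folds(labels, folds, seed)
  D2 <- cross_dist2(X)
  cells <- expand.grid(b = b_range, a = a_range)[, c("a", "b")]
  acc <- matrix(NA_real_, nrow(cells), 2L)
  for (ai in seq_along(a_range)) {
    K <- exp(-D2 / 10^a_range[ai])
    for (bi in seq_along(b_range)) {
      row <- (ai - 1L) * length(b_range) + bi
      fa <- lssvm_cv_kernel(K, labels, 10^b_range[bi], folds_idx)
      acc[row, ] <- c(mean(fa), stats::sd(fa))
    }
  }
  grid <- data.frame(a = cells$a, b = cells$b,
                     sigma2 = 10^cells$a, gamma = 10^cells$b,
                     mean_acc = acc[, 1L], sd_acc = acc[, 2L])
  ord <- order(-grid$mean_acc, grid$a, grid$b)
  structure(list(grid = grid, best = grid[ord[1L], ],
                 folds = as.integer(folds), seed = as.integer(seed),
                 fold_assignment = folds_idx),
            class = "grid_search_report")
}

#' @export
print.grid_search_report <- function(x, ...) {
  cat(sprintf("<grid_search_report> %d cells, %d-fold CV\n",
              nrow(x$grid), x$folds))
  cat(sprintf("  best: a = %g, b = %g (sigma2 = %g, gamma = %g), accuracy %.4f +/- %.4f\n",
              x$best$a, x$best$b, x$best$sigma2, x$best$gamma,
              x$best$mean_acc, x$best$sd_acc))
  invisible(x)
}

#' Write a grid-search report as TSV
#'
#' @param report a [grid_search()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_grid_report <- function(report, path) {
  utils::write.table(report$grid, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Score a feature subset with a tuned LS-SVM
#'
#' Restricts the training (and optional test) samples to the subset's
#' columns — mixed features are recomputed on each dataset from the stored
#' group definitions — tunes `(sigma2, gamma)` by grid search under
#' stratified CV on the training samples, and reports the CV accuracy
#' (mean +/- sd over folds) at the best cell plus, when `test_ds` is
#' given, the held-out accuracy of the model refit on all training
#' samples.
#'
#' @param train_ds a [clinical_dataset()] of training samples.
#' @param test_ds optional held-out [clinical_dataset()].
#' @param subset a [assemble_subset()] result, or `NULL` to use all
#'   original symptoms.
#' @param a_range,b_range,folds,seed grid-search settings.
#' @return list with `grid` (the report), `best`, `cv_mean`, `cv_sd`,
#'   `test_accuracy` (or `NA`), `n_features`.
#' @export
evaluate_subset <- function(train_ds, test_ds = NULL, subset = NULL,
                            a_range = default_grid()$a,
                            b_range = default_grid()$b,
                            folds = 5L, seed = 1L) {
  stopifnot(inherits(train_ds, "clinical_dataset"))
  Xtr <- if (is.null(subset)) train_ds$values else
    apply_subset(subset, train_ds)
  if (ncol(Xtr) == 0L)
    ns_abort("empty feature subset", "ns_validation_error")
  report <- grid_search(Xtr, train_ds$stage, a_range, b_range, folds, seed)
  test_accuracy <- NA_real_
  if (!is.null(test_ds)) {
    Xte <- if (is.null(subset)) test_ds$values[, colnames(Xtr), drop = FALSE]
           else apply_subset(subset, test_ds)
    model <- lssvm_multiclass(Xtr, train_ds$stage,
                              report$best$sigma2, report$best$gamma)
    test_accuracy <- mean(predict(model, Xte) == test_ds$stage)
  }
  list(grid = report, best = report$best,
       cv_mean = report$best$mean_acc, cv_sd = report$best$sd_acc,
       test_accuracy = test_accuracy, n_features = ncol(Xtr))
}
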