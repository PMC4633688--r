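#' Distance-based similarity of basis rows
#'
#' For rows `w_i` of the basis matrix W, `d2(i, j)` is the squared
#' Euclidean distance and `MaxD` the maximum over all pairs;
#' `sim_dist(i, j) = 1 - d2(i, j) / MaxD`, so identical rows score 1 and
#' the most distant pair scores exactly 0.
#'
#' @param W basis matrix, features in rows (>= 2 rows, not all identical).
#' @return symmetric n x n matrix in [0, 1] with unit diagonal, plus the
#'   normalizer as attribute `"max_d"`.
#' @export
sim_dist_matrix <- function(W) {
  W <- as.matrix(W)
  if (nrow(W) < 2L)
    ns_abort("need at least two features", "ns_validation_error")
  d2 <- as.matrix(stats::dist(W))^2
  max_d <- max(d2)
  if (max_d == 0)
    ns_abort("all basis rows identical: distance geometry is degenerate",
             "ns_degenerate_error")
  s <- 1 - d2 / max_d
  dimnames(s) <- list(rownames(W), rownames(W))
  attr(s, "max_d") <- max_d
  s
}

#' Correlation-based similarity of basis rows
#'
#' Pearson correlation between rows of W, each centered by its own mean.
#' Proportional rows (`w_i = k w_j`) score 1: they induce proportional
#' reconstructed feature profiles. Constant rows have undefined
#' correlation; their entries are `NA` and a warning is raised (such
#' features are excluded from redundancy grouping).
#'
#' @param W basis matrix, features in rows.
#' @return symmetric n x n matrix in [-1, 1] with unit diagonal.
#' @export
sim_corr_matrix <- function(W) {
  W <- as.matrix(W)
  constant <- apply(W, 1L, function(r) stats::sd(r) == 0)
  if (any(constant))
    warning("constant basis row(s): correlation undefined for ",
            paste(rownames(W)[constant], collapse = ", "))
  s <- suppressWarnings(stats::cor(t(W)))
  diag(s) <- 1
  dimnames(s) <- list(rownames(W), rownames(W))
  s
}

#' Combined similarity (SMX)
#'
#' Elementwise arithmetic mean of the distance- and correlation-based
#' similarities.
#'
#' @param sd_mat,sc_mat matrices from [sim_dist_matrix()] and
#'   [sim_corr_matrix()], same shape.
#' @return the combined matrix.
#' @export
combined_similarity <- function(sd_mat, sc_mat) {
  stopifnot(all(dim(sd_mat) == dim(sc_mat)))
  (sd_mat + sc_mat) / 2
}

#' All three similarity matrices of a basis matrix
#'
#' @param W basis matrix, features in rows.
#' @return a `similarity_matrices` object: `sim_dist`, `sim_corr`, `smx`,
#'   `max_d`, and `constant` (ids of constant rows, excluded from
#'   grouping).
#' @export
similarity_matrices <- function(W) {
  sd_mat <- sim_dist_matrix(W)
  sc_mat <- sim_corr_matrix(W)
  constant <- rownames(W)[apply(as.matrix(W), 1L,
                                function(r) stats::sd(r) == 0)]
  structure(list(sim_dist = sd_mat, sim_corr = sc_mat,
                 smx = combined_similarity(sd_mat, sc_mat),
                 max_d = attr(sd_mat, "max_d"),
                 constant = constant),
            class = "similarity_matrices")
}

#' @export
print.similarity_matrices <- function(x, ...) {
  cat(sprintf("<similarity_matrices> %d features, MaxD = %.4g\n",
              nrow(x$smx), x$max_d))
  invisible(x)
}

#' Infer redundant symptom groups from basis-row similarities
#'
#' Builds a graph over features with an edge (i, j) when the pair clears
#' the similarity threshold and (by default) both features relate to the
#' same basis; redundant groups are the connected components of size >= 2.
#' The default `"dual"` rule requires `sim_dist >= theta` AND
#' `sim_corr >= theta`; the `"smx"` rule thresholds the combined
#' similarity `SMX > theta` instead.
#'
#' @param sims a [similarity_matrices()] object.
#' @param basis_of integer basis index per feature (from
#'   [assign_feature_basis()]); required when `same_basis = TRUE`.
#' @param theta threshold in (0, 1); default 0.95.
#' @param rule `"dual"` (default) or `"smx"`.
#' @param same_basis restrict edges to features sharing a basis (default
#'   TRUE).
#' @return a `redundancy_groups` object: list of groups, each with
#'   `members`, `basis`, `mean_sim_dist`, `mean_sim_corr`; plus the
#'   thresholding settings. Empty result allowed.
#' @export
find_redundant_groups <- function(sims, basis_of = NULL, theta = 0.95,
                                  rule = c("dual", "smx"),
                                  same_basis = TRUE) {
  stopifnot(inherits(sims, "similarity_matrices"))
  rule <- match.arg(rule)
  ns_stopifnot_scalar_prob(theta, "theta")
  ids <- rownames(sims$smx)
  n <- length(ids)
  adj <- switch(rule,
                dual = (sims$sim_dist >= theta) & (sims$sim_corr >= theta),
                smx = sims$smx > theta)
  adj[is.na(adj)] <- FALSE
  if (length(sims$constant)) {
    drop <- ids %in% sims$constant
    adj[drop, ] <- FALSE
    adj[, drop] <- FALSE
  }
  if (same_basis) {
    if (is.null(basis_of))
      ns_abort("`basis_of` is required when `same_basis = TRUE`",
               "ns_config_error")
    basis_of <- basis_of[ids]
    adj <- adj & outer(basis_of, basis_of, "==")
  }
  diag(adj) <- FALSE

  # connected components by BFS
  comp <- integer(n)
  ncomp <- 0L
  for (i in seq_len(n)) {
    if (comp[i] != 0L) next
    ncomp <- ncomp + 1L
    queue <- i
    comp[i] <- ncomp
    while (length(queue)) {
      v <- queue[[1L]]; queue <- queue[-1L]
      nb <- which(adj[v, ] & comp == 0L)
      comp[nb] <- ncomp
      queue <- c(queue, nb)
    }
  }
  groups <- list()
  for (k in seq_len(ncomp)) {
    members <- which(comp == k)
    if (length(members) < 2L) next
    pairs <- utils::combn(members, 2L)
    groups[[length(groups) + 1L]] <- list(
      members = ids[members],
      basis = if (same_basis) unname(basis_of[members[1L]]) else {
        b <- if (!is.null(basis_of)) unique(basis_of[members]) else integer()
        if (length(b) == 1L) unname(b) else NA_integer_
      },
      mean_sim_dist = mean(sims$sim_dist[t(pairs)]),
      mean_sim_corr = mean(sims$sim_corr[t(pairs)])
    )
  }
  ord <- order(vapply(groups, function(g) {
    1000 * (if (is.na(g$basis)) 999 else g$basis) +
      match(g$members[1L], ids)
  }, numeric(1)))
  structure(list(groups = groups[ord], theta = theta, rule = rule,
                 same_basis = same_basis),
            class = "redundancy_groups")
}

#' @export
print.redundancy_groups <- function(x, ...) {
  cat(sprintf("<redundancy_groups> %d group(s), theta = %g, rule = %s\n",
              length(x$groups), x$theta, x$rule))
  for (g in x$groups)
    cat(sprintf("  basis %s: {%s}  sim_dist %.4f  sim_corr %.4f\n",
                g$basis, paste(g$members, collapse = ", "),
                g$mean_sim_dist, g$mean_sim_corr))
  invisible(x)
}

#' Compress one redundant group into a mixed feature
#'
#' Strategy `"mean"` averages the member columns elementwise; strategy
#' `"representative"` picks one member column uniformly at random under
#' `seed` (the chosen member is recorded so the feature can be recomputed
#' on other datasets).
#'
#' @param X samples x features matrix (or [clinical_dataset()] values).
#' @param group character vector of member feature ids (>= 2).
#' @param strategy `"mean"` (default) or `"representative"`.
#' @param seed RNG seed for the representative choice.
#' @param id identifier for the new feature (assigned by
#'   [assemble_subset()], e.g. `"M11"`).
#' @return list with `id`, `values`, `members`, `strategy`, and, for the
#'   representative strategy, `chosen`.
#' @export
build_mixed_feature <- function(X, group, strategy = c("mean", "representative"),
                                seed = 1L, id = NULL) {
  strategy <- tryCatch(match.arg(strategy),
                       error = function(e)
                         ns_abort("unknown mixed-feature strategy",
                                  "ns_config_error"))
  if (inherits(X, "clinical_dataset")) X <- X$values
  group <- as.character(group)
  if (length(group) < 2L)
    ns_abort("a redundant group needs at least two members",
             "ns_validation_error")
  if (!all(group %in% colnames(X)))
    ns_abort("group member(s) missing from the data", "ns_key_error")
  cols <- X[, group, drop = FALSE]
  if (strategy == "mean") {
    vals <- rowMeans(cols)
    chosen <- NULL
  } else {
    chosen <- group[ns_with_seed(seed, sample.int(length(group), 1L))]
    vals <- cols[, chosen]
  }
  list(id = id, values = unname(vals), members = group,
       strategy = strategy, chosen = chosen)
}

#' Assemble the selected feature subset
#'
#' The transformed dataset keeps every non-grouped original symptom (order
#' preserved) and appends one mixed feature per redundant group, named
#' `M<basis><ordinal>` with a per-basis ordinal. The counts satisfy
#' `kept + mixed = n - sum(group sizes) + #groups`.
#'
#' @param ds a [clinical_dataset()] holding the relevant symptoms.
#' @param groups a [find_redundant_groups()] result (groups must be
#'   disjoint and within the dataset).
#' @param strategy mixed-feature strategy, see [build_mixed_feature()].
#' @param seed seed for representative choices.
#' @return a `feature_subset`: `kept` (original ids), `mixed` (list of
#'   mixed-feature definitions), `values` (samples x selected features),
#'   `feature_ids`, `stage`, `substage`, `sex`, `strategy`.
#' @export
assemble_subset <- function(ds, groups, strategy = c("mean", "representative"),
                            seed = 1L) {
  stopifnot(inherits(ds, "clinical_dataset"),
            inherits(groups, "redundancy_groups"))
  strategy <- tryCatch(match.arg(strategy),
                       error = function(e)
                         ns_abort("unknown mixed-feature strategy",
                                  "ns_config_error"))
  member_ids <- unlist(lapply(groups$groups, `[[`, "members"))
  if (anyDuplicated(member_ids))
    ns_abort("redundant groups overlap", "ns_validation_error")
  if (!all(member_ids %in% colnames(ds$values)))
    ns_abort("group member(s) missing from the dataset", "ns_key_error")
  kept <- setdiff(colnames(ds$values), member_ids)
  seeds <- ns_derive_seeds(seed, max(1L, length(groups$groups)))
  counter <- integer(0)
  mixed <- list()
  for (i in seq_along(groups$groups)) {
    g <- groups$groups[[i]]
    b <- as.character(if (is.na(g$basis)) 0L else g$basis)
    counter[b] <- if (is.null(counter[b]) || is.na(counter[b])) 1L
                  else counter[b] + 1L
    mid <- paste0("M", b, counter[b])
    mixed[[i]] <- build_mixed_feature(ds, g$members, strategy,
                                      seed = seeds[i], id = mid)
    mixed[[i]]$basis <- g$basis
  }
  mixed_vals <- if (length(mixed))
    do.call(cbind, lapply(mixed, `[[`, "values")) else
    matrix(numeric(0), nrow(ds$values), 0L)
  values <- cbind(ds$values[, kept, drop = FALSE], mixed_vals)
  feature_ids <- c(kept, vapply(mixed, `[[`, character(1), "id"))
  colnames(values) <- feature_ids
  structure(list(kept = kept, mixed = mixed, values = values,
                 feature_ids = feature_ids, stage = ds$stage,
                 substage = ds$substage, sex = ds$sex,
                 strategy = strategy),
            class = "feature_subset")
}

#' @export
print.feature_subset <- function(x, ...) {
  cat(sprintf("<feature_subset> %d features (%d original + %d mixed), %d samples\n",
              length(x$feature_ids), length(x$kept), length(x$mixed),
              nrow(x$values)))
  invisible(x)
}

#' Recompute a feature subset on another dataset
#'
#' Applies the stored group definitions (and, for the representative
#' strategy, the stored member choices) to a dataset containing the same
#' original symptoms, e.g. held-out test samples.
#'
#' @param subset a [assemble_subset()] result.
#' @param ds a [clinical_dataset()] containing all required symptoms.
#' @return samples x features numeric matrix in the subset's column order.
#' @export
apply_subset <- function(subset, ds) {
  stopifnot(inherits(subset, "feature_subset"),
            inherits(ds, "clinical_dataset"))
  needed <- c(subset$kept, unlist(lapply(subset$mixed, `[[`, "members")))
  if (!all(needed %in% colnames(ds$values)))
    ns_abort("dataset lacks symptom(s) required by the subset",
             "ns_validation_error")
  mixed_vals <- lapply(subset$mixed, function(m) {
    if (m$strategy == "mean") rowMeans(ds$values[, m$members, drop = FALSE])
    else ds$values[, m$chosen]
  })
  values <- cbind(ds$values[, subset$kept, drop = FALSE],
                  if (length(mixed_vals)) do.call(cbind, mixed_vals))
  colnames(values) <- subset$feature_ids
  values
}

#' Write a similarity matrix as TSV with symptom-id headers
#'
#' @param mat matrix with dimnames.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_similarity <- function(mat, path) {
  df <- data.frame(symptom = rownames(mat), mat, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write redundancy groups as a JSON report
#'
#' @param groups a [find_redundant_groups()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_groups <- function(groups, path) {
  rep <- list(theta = groups$theta, rule = groups$rule,
              groups = lapply(seq_along(groups$groups), function(i) {
                g <- groups$groups[[i]]
                list(id = i, basis = g$basis, members = g$members,
                     mean_sim_dist = g$mean_sim_dist,
                     mean_sim_corr = g$mean_sim_corr)
              }))
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
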