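#' Per-class centroid symptom vectors
#'
#' The centroid of a class is the arithmetic mean of the symptom vectors
#' of its samples.
#'
#' @param ds a [clinical_dataset()].
#' @return numeric matrix, one row per class (rownames = class labels).
#' @export
class_centroids <- function(ds) {
  stopifnot(inherits(ds, "clinical_dataset"))
  classes <- sort(unique(ds$stage))
  cent <- t(vapply(classes,
                   function(cl) colMeans(ds$values[ds$stage == cl, ,
                                                   drop = FALSE]),
                   numeric(ncol(ds$values))))
  rownames(cent) <- classes
  cent
}

#' Select a class- and covariate-balanced representative subset
#'
#' Within each class (and, when `balance` names a covariate, within each
#' covariate level) samples are ranked by ascending Euclidean distance to
#' their class centroid and the top quota is taken. Distance ties break by
#' ascending sample id, so the selection is deterministic. This is the
#' centroid-nearest-neighbour reading of representative sampling: the
#' samples closest to the class mean are the most typical of the class.
#'
#' @param ds a [clinical_dataset()].
#' @param per_class samples to take from each class (default 40).
#' @param balance name of the covariate to balance (`"sex"`), or `NULL`
#'   for no balancing.
#' @param ratio named integer vector of per-level quotas summing to
#'   `per_class`; default splits `per_class` equally across levels
#'   (e.g. 20:20 for two sexes).
#' @return a `representative_selection`: list with `ids`, `dataset` (the
#'   subset), `centroids`, `distances` (named, per selected sample),
#'   `per_class`, `balance`, `ratio`.
#' @export
select_representatives <- function(ds, per_class = 40, balance = NULL,
                                   ratio = NULL) {
  stopifnot(inherits(ds, "clinical_dataset"))
  per_class <- as.integer(per_class)
  if (per_class < 1L)
    ns_abort("`per_class` must be a positive count", "ns_config_error")
  cent <- class_centroids(ds)
  classes <- rownames(cent)

  covariate <- NULL
  if (!is.null(balance)) {
    covariate <- switch(balance, sex = ds$sex,
                        ns_abort(paste0("unknown covariate: ", balance),
                                 "ns_config_error"))
    if (is.null(covariate))
      ns_abort(sprintf("dataset has no `%s` covariate", balance),
               "ns_config_error")
    levels <- sort(unique(covariate))
    if (is.null(ratio)) {
      if (per_class %% length(levels) != 0L)
        ns_abort("`per_class` not divisible across covariate levels; give `ratio`",
                 "ns_config_error")
      ratio <- stats::setNames(rep(per_class %/% length(levels),
                                   length(levels)), levels)
    }
    if (!setequal(names(ratio), levels) || sum(ratio) != per_class)
      ns_abort("`ratio` must cover every covariate level and sum to `per_class`",
               "ns_config_error")
  }

  all_ids <- character(0)
  all_dist <- numeric(0)
  for (cl in classes) {
    in_class <- ds$stage == as.integer(cl)
    d2 <- colSums((t(ds$values[in_class, , drop = FALSE]) - cent[cl, ])^2)
    dist <- sqrt(d2)
    ids <- rownames(ds$values)[in_class]
    cells <- if (is.null(covariate)) {
      stats::setNames(list(seq_along(ids)), "")
    } else {
      lev <- covariate[in_class]
      lapply(stats::setNames(names(ratio), names(ratio)),
             function(l) which(lev == l))
    }
    for (ci in seq_along(cells)) {
      cell <- names(cells)[ci]
      idx <- cells[[ci]]
      quota <- if (is.null(covariate)) per_class else ratio[[cell]]
      if (length(idx) < quota)
        ns_abort(sprintf(
          "class %s%s has %d samples but %d were requested", cl,
          if (nzchar(cell)) paste0(", level ", cell) else "",
          length(idx), quota), "ns_quota_error")
      ord <- idx[order(dist[idx], ids[idx])]
      take <- ord[seq_len(quota)]
      all_ids <- c(all_ids, ids[take])
      all_dist <- c(all_dist, stats::setNames(dist[take], ids[take]))
    }
  }
  structure(list(ids = all_ids,
                 dataset = subset_samples(ds, all_ids),
                 centroids = cent,
                 distances = all_dist,
                 per_class = per_class,
                 balance = balance,
                 ratio = ratio),
            class = "representative_selection")
}

#' @export
print.representative_selection <- function(x, ...) {
  cat(sprintf("<representative_selection> %d samples (%d per class)\n",
              length(x$ids), x$per_class))
  invisible(x)
}
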