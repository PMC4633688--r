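#' Stage-stratified positive frequencies of each symptom
#'
#' A symptom is positive for a patient when its severity code is strictly
#' greater than zero, regardless of the level. For each stratum (substage
#' when available, else coarse stage) the positive frequency of a symptom
#' is the fraction of the stratum's samples on which it is positive.
#'
#' @param ds a [clinical_dataset()].
#' @param stratify_by `"auto"` (substages when present, the finest
#'   available labels), `"substage"`, or `"stage"`.
#' @return a `frequency_table`: list with `freq` (symptoms x strata matrix
#'   of fractions), `strata_ids`, and `counts` (per-stratum sample counts).
#' @export
positive_frequencies <- function(ds,
                                 stratify_by = c("auto", "substage", "stage")) {
  stopifnot(inherits(ds, "clinical_dataset"))
  stratify_by <- match.arg(stratify_by)
  if (stratify_by == "auto")
    stratify_by <- if (!is.null(ds$substage)) "substage" else "stage"
  labels <- switch(stratify_by,
                   substage = {
                     if (is.null(ds$substage))
                       ns_abort("dataset has no substage labels",
                                "ns_strat_error")
                     ds$substage
                   },
                   stage = as.character(ds$stage))
  strata <- sort(unique(labels))
  counts <- vapply(strata, function(s) sum(labels == s), integer(1))
  if (any(counts == 0L))
    ns_abort("empty stratum", "ns_strat_error")
  pos <- ds$values > 0
  freq <- vapply(strata, function(s) colMeans(pos[labels == s, , drop = FALSE]),
                 numeric(ncol(ds$values)))
  freq <- matrix(freq, nrow = ncol(ds$values),
                 dimnames = list(colnames(ds$values), strata))
  structure(list(freq = freq, strata_ids = strata, counts = counts,
                 stratify_by = stratify_by),
            class = "frequency_table")
}

#' @export
print.frequency_table <- function(x, ...) {
  cat(sprintf("<frequency_table> %d symptoms x %d strata (%s)\n",
              nrow(x$freq), length(x$strata_ids), x$stratify_by))
  invisible(x)
}

#' Identify irrelevant symptoms from a frequency table
#'
#' A symptom is irrelevant when its positive frequency is strictly below
#' `threshold` in every stratum: such a symptom hardly ever appears
#' positive in any class of patients and contributes nothing to
#' stratification. Ties at exactly the threshold are kept.
#'
#' @param ft a [positive_frequencies()] table.
#' @param threshold fraction in (0, 1); default 0.10.
#' @return character vector of flagged symptom ids, in symptom order.
#' @export
find_irrelevant <- function(ft, threshold = 0.10) {
  stopifnot(inherits(ft, "frequency_table"))
  ns_stopifnot_scalar_prob(threshold, "threshold")
  flagged <- apply(ft$freq < threshold, 1L, all)
  rownames(ft$freq)[flagged]
}

#' Remove symptoms by id
#'
#' @param ds a [clinical_dataset()].
#' @param ids symptom ids to drop; every id must exist.
#' @return the dataset without those columns; labels untouched.
#' @export
remove_features <- function(ds, ids) {
  stopifnot(inherits(ds, "clinical_dataset"))
  ids <- as.character(ids)
  if (!length(ids)) return(ds)
  unknown <- setdiff(ids, colnames(ds$values))
  if (length(unknown))
    ns_abort(paste0("unknown symptom id(s): ", paste(unknown, collapse = ", ")),
             "ns_key_error")
  keep <- setdiff(colnames(ds$values), ids)
  if (!length(keep))
    ns_abort("removing all symptoms would leave an empty dataset",
             "ns_empty_error")
  ds$values <- ds$values[, keep, drop = FALSE]
  ds
}
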