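#' Construct a clinical symptom dataset
#'
#' A `clinical_dataset` holds a samples x symptoms matrix of nonnegative
#' integer severity codes (0 = symptom absent; larger values = stronger
#' positive state), one clinical-stage class per sample, optionally the
#' finer substage code it was derived from, and an optional binary sex
#' covariate.
#'
#' @param values numeric matrix, samples in rows, symptoms in columns;
#'   every entry must be a nonnegative integer and no entry may be missing.
#' @param symptom_ids,sample_ids unique identifier vectors; default to the
#'   dimnames of `values` or to `V1..Vn` / `S1..Sp`.
#' @param substage per-sample substage code (e.g. `"IA"`), or `NULL`.
#' @param stage per-sample integer class; derived from `substage` via
#'   `substage_map` when omitted.
#' @param sex optional per-sample covariate (any two-or-more-level coding).
#' @param substage_map named vector mapping substage codes to stages; see
#'   [default_substage_map()].
#' @return an object of class `clinical_dataset` with fields `values`
#'   (integer matrix with ids as dimnames), `stage`, `substage`, `sex`.
#' @seealso [read_dataset()], [relabel_substages()], [drop_constant_features()]
#' @export
clinical_dataset <- function(values, symptom_ids = NULL, sample_ids = NULL,
                             substage = NULL, stage = NULL, sex = NULL,
                             substage_map = default_substage_map()) {
  values <- as.matrix(values)
  if (length(values) == 0L)
    ns_abort("dataset has no entries", "ns_empty_error")
  if (!is.numeric(values) || anyNA(values))
    ns_abort("symptom values must be numeric with no missing entries",
             "ns_validation_error")
  if (any(values < 0) || !all(ns_is_wholenumber(values)))
    ns_abort("symptom values must be nonnegative integers",
             "ns_validation_error")
  p <- nrow(values); n <- ncol(values)
  if (is.null(symptom_ids)) symptom_ids <- colnames(values)
  if (is.null(symptom_ids)) symptom_ids <- paste0("V", seq_len(n))
  if (is.null(sample_ids)) sample_ids <- rownames(values)
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(p))
  symptom_ids <- as.character(symptom_ids)
  sample_ids <- as.character(sample_ids)
  if (length(symptom_ids) != n || anyDuplicated(symptom_ids))
    ns_abort("symptom ids must be unique and match the number of columns",
             "ns_validation_error")
  if (length(sample_ids) != p || anyDuplicated(sample_ids))
    ns_abort("sample ids must be unique and match the number of rows",
             "ns_validation_error")
  storage.mode(values) <- "integer"
  dimnames(values) <- list(sample_ids, symptom_ids)

  if (!is.null(substage)) {
    substage <- as.character(substage)
    if (length(substage) != p)
      ns_abort("substage must have one code per sample", "ns_validation_error")
  }
  if (is.null(stage)) {
    if (is.null(substage))
      ns_abort("either `stage` or `substage` must be supplied",
               "ns_format_error")
    stage <- map_substage(substage, substage_map)
  } else {
    stage <- as.integer(stage)
    if (length(stage) != p || anyNA(stage))
      ns_abort("stage must have one integer class per sample",
               "ns_validation_error")
    if (!is.null(substage)) {
      implied <- map_substage(substage, substage_map)
      if (!all(implied == stage))
        ns_abort("stage labels are inconsistent with the substage map",
                 "ns_validation_error")
    }
  }
  if (!is.null(sex)) {
    sex <- as.character(sex)
    if (length(sex) != p || anyNA(sex))
      ns_abort("sex must have one code per sample", "ns_validation_error")
  }
  structure(list(values = values, stage = stage, substage = substage,
                 sex = sex),
            class = "clinical_dataset")
}

#' Default substage-to-stage relabeling map
#'
#' The six-substage staging vocabulary collapses to three classes:
#' IA/IB -> 1, IIA/IIB -> 2, IIIA/IIIB -> 3.
#'
#' @return named integer vector.
#' @export
default_substage_map <- function() {
  c(IA = 1L, IB = 1L, IIA = 2L, IIB = 2L, IIIA = 3L, IIIB = 3L)
}

map_substage <- function(substage, map) {
  unknown <- setdiff(unique(substage), names(map))
  if (length(unknown))
    ns_abort(paste0("substage code(s) not in map: ",
                    paste(unknown, collapse = ", ")),
             "ns_label_error")
  as.integer(unname(map[substage]))
}

#' Relabel substages to coarse stage classes
#'
#' Populates the `stage` field from the `substage` codes; the symptom
#' matrix is untouched.
#'
#' @param ds a [clinical_dataset()].
#' @param map named substage -> class vector; default [default_substage_map()].
#' @return the dataset with `stage` rewritten.
#' @export
relabel_substages <- function(ds, map = default_substage_map()) {
  stopifnot(inherits(ds, "clinical_dataset"))
  if (is.null(ds$substage))
    ns_abort("dataset has no substage labels to relabel", "ns_label_error")
  ds$stage <- map_substage(ds$substage, map)
  ds
}

#' Remove symptoms that are constant across all samples
#'
#' A symptom whose column takes a single value on every sample carries no
#' information for stratifying patients and is dropped before any analysis.
#'
#' @param ds a [clinical_dataset()].
#' @return list with `dataset` (constant columns removed, order of the
#'   rest preserved) and `removed` (character vector of dropped ids).
#' @export
drop_constant_features <- function(ds) {
  stopifnot(inherits(ds, "clinical_dataset"))
  v <- ds$values
  constant <- apply(v, 2L, function(col) all(col == col[1L]))
  if (all(constant))
    ns_abort("all symptoms are constant; nothing would remain",
             "ns_empty_error")
  removed <- colnames(v)[constant]
  if (length(removed)) ds$values <- v[, !constant, drop = FALSE]
  list(dataset = ds, removed = removed)
}

#' Subset a clinical dataset by sample ids
#'
#' @param ds a [clinical_dataset()].
#' @param ids sample ids to keep, in the requested order.
#' @return the subset dataset.
#' @export
subset_samples <- function(ds, ids) {
  stopifnot(inherits(ds, "clinical_dataset"))
  idx <- match(ids, rownames(ds$values))
  if (anyNA(idx))
    ns_abort("unknown sample id(s)", "ns_key_error")
  ds$values <- ds$values[idx, , drop = FALSE]
  ds$stage <- ds$stage[idx]
  if (!is.null(ds$substage)) ds$substage <- ds$substage[idx]
  if (!is.null(ds$sex)) ds$sex <- ds$sex[idx]
  ds
}

infer_delim <- function(path, delim) {
  if (!is.null(delim)) return(delim)
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Read a clinical dataset from delimited text
#'
#' The canonical on-disk layout is samples as rows: a `sample_id` column,
#' the label columns, then one column per symptom. `orientation =
#' "features"` accepts the transposed layout (symptoms as rows, samples as
#' header columns, label rows named by the label-column names).
#'
#' @param path file path; delimiter inferred from the extension (`.csv` ->
#'   comma, otherwise tab) unless `delim` is given.
#' @param delim field delimiter override.
#' @param orientation `"samples"` (default) or `"features"`.
#' @param id_col,substage_col,stage_col,sex_col column (or, transposed,
#'   row) names carrying identifiers and labels.
#' @param substage_map map used to derive/validate stages.
#' @return a [clinical_dataset()].
#' @export
read_dataset <- function(path, delim = NULL,
                         orientation = c("samples", "features"),
                         id_col = "sample_id", substage_col = "substage",
                         stage_col = "stage", sex_col = "sex",
                         substage_map = default_substage_map()) {
  orientation <- match.arg(orientation)
  if (!file.exists(path))
    ns_abort(paste0("file not found: ", path), "ns_format_error")
  delim <- infer_delim(path, delim)
  raw <- utils::read.table(path, sep = delim, header = TRUE,
                           check.names = FALSE, colClasses = "character",
                           na.strings = character())
  if (orientation == "features") {
    rid <- raw[[1L]]
    mat <- t(as.matrix(raw[, -1L, drop = FALSE]))
    colnames(mat) <- rid
    raw <- data.frame(sample_id = rownames(mat), mat, check.names = FALSE,
                      stringsAsFactors = FALSE)
    names(raw)[1L] <- id_col
  }
  cols <- names(raw)
  if (!id_col %in% cols) {
    names(raw)[1L] <- id_col
    cols <- names(raw)
  }
  has_sub <- substage_col %in% cols
  has_stage <- stage_col %in% cols
  if (!has_sub && !has_stage)
    ns_abort(sprintf("no label column: expected `%s` or `%s`",
                     substage_col, stage_col), "ns_format_error")
  label_cols <- c(id_col, intersect(c(substage_col, stage_col, sex_col), cols))
  symptom_cols <- setdiff(cols, label_cols)
  if (!length(symptom_cols))
    ns_abort("no symptom columns present", "ns_format_error")
  vals <- raw[, symptom_cols, drop = FALSE]
  if (any(vals == "" | is.na(as.matrix(vals))))
    ns_abort("empty symptom cell; missing values are not supported",
             "ns_validation_error")
  num <- suppressWarnings(vapply(vals, as.numeric, numeric(nrow(raw))))
  num <- matrix(num, nrow = nrow(raw),
                dimnames = list(NULL, symptom_cols))
  if (anyNA(num))
    ns_abort("non-numeric symptom value", "ns_validation_error")
  clinical_dataset(
    num,
    symptom_ids = symptom_cols,
    sample_ids = raw[[id_col]],
    substage = if (has_sub) raw[[substage_col]] else NULL,
    stage = if (has_stage) as.integer(raw[[stage_col]]) else NULL,
    sex = if (sex_col %in% cols) raw[[sex_col]] else NULL,
    substage_map = substage_map
  )
}

#' Write a clinical dataset as delimited text
#'
#' Emits the canonical samples-as-rows layout read back by
#' [read_dataset()]; the round trip is exact.
#'
#' @param ds a [clinical_dataset()].
#' @param path output path; delimiter inferred from extension unless given.
#' @param delim field delimiter override.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(ds, path, delim = NULL) {
  stopifnot(inherits(ds, "clinical_dataset"))
  delim <- infer_delim(path, delim)
  df <- data.frame(sample_id = rownames(ds$values),
                   stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(ds$substage)) df$substage <- ds$substage
  df$stage <- ds$stage
  if (!is.null(ds$sex)) df$sex <- ds$sex
  df <- cbind(df, as.data.frame(ds$values, check.names = FALSE))
  utils::write.table(df, path, sep = delim, quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @export
print.clinical_dataset <- function(x, ...) {
  cat(sprintf("<clinical_dataset> %d samples x %d symptoms\n",
              nrow(x$values), ncol(x$values)))
  tab <- table(x$stage)
  cat("  stages: ", paste(sprintf("%s (n=%d)", names(tab), tab),
                          collapse = ", "), "\n", sep = "")
  if (!is.null(x$substage)) cat("  substages present\n")
  if (!is.null(x$sex)) cat("  sex covariate present\n")
  invisible(x)
}

#' Number of samples / symptoms
#' @param ds a [clinical_dataset()].
#' @return integer count.
#' @export
n_samples <- function(ds) nrow(ds$values)

#' @rdname n_samples
#' @export
n_symptoms <- function(ds) ncol(ds$values)
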