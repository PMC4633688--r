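#' Pipeline configuration
#'
#' Bundles every tunable of the end-to-end feature-selection run:
#' screening threshold, representative-sampling quotas, NMF settings and
#' rank range, redundancy threshold and grouping rule, mixed-feature
#' strategy, and the LS-SVM validation grid. One master `seed` derives the
#' per-stage seeds by fixed offsets, so stages are independently
#' re-runnable.
#'
#' @param freq_threshold irrelevance screening threshold (default 0.10).
#' @param stratify_by screening strata; default `"stage"` (the three
#'   coarse classes, matching the "low in each clinical stage" rule;
#'   substage strata can be tiny and make the frequency estimate noisy).
#'   `"substage"` and `"auto"` are accepted.
#' @param per_class representative samples per class (default 40).
#' @param balance covariate to balance, or `NULL` (default `"sex"`).
#' @param ratio per-level quotas (default equal split, i.e. 20:20).
#' @param rank_range candidate NMF ranks (default 2:7).
#' @param n_runs NMF restarts per rank for the consensus (default 30).
#' @param nmf an [nmf_config()] supplying update settings.
#' @param theta redundancy similarity threshold (default 0.95).
#' @param rule grouping rule, `"dual"` or `"smx"`.
#' @param same_basis restrict groups to one basis (default TRUE).
#' @param strategy mixed-feature strategy (default `"mean"`).
#' @param a_range,b_range,folds LS-SVM validation grid and CV folds.
#' @param validate run the LS-SVM scoring stage (default TRUE).
#' @param out_dir directory for artifact files, or `NULL` to skip writing.
#' @param seed master seed.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(freq_threshold = 0.10,
                            stratify_by = "stage",
                            per_class = 40L,
                            balance = "sex",
                            ratio = NULL,
                            rank_range = 2:7,
                            n_runs = 30L,
                            nmf = nmf_config(),
                            theta = 0.95,
                            rule = "dual",
                            same_basis = TRUE,
                            strategy = "mean",
                            a_range = default_grid()$a,
                            b_range = default_grid()$b,
                            folds = 5L,
                            validate = TRUE,
                            out_dir = NULL,
                            seed = 1L) {
  ns_stopifnot_scalar_prob(freq_threshold, "freq_threshold")
  ns_stopifnot_scalar_prob(theta, "theta")
  structure(list(freq_threshold = freq_threshold, stratify_by = stratify_by,
                 per_class = as.integer(per_class), balance = balance,
                 ratio = ratio, rank_range = as.integer(rank_range),
                 n_runs = as.integer(n_runs), nmf = nmf, theta = theta,
                 rule = rule, same_basis = same_basis, strategy = strategy,
                 a_range = a_range, b_range = b_range,
                 folds = as.integer(folds), validate = validate,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "pipeline_config")
}

config_hash <- function(cfg) {
  ns_hash(jsonlite::toJSON(cfg[setdiff(names(cfg), "out_dir")],
                           auto_unbox = TRUE, digits = NA, force = TRUE))
}

pipeline_log <- function(verbose, stage, fmt, ...) {
  if (verbose)
    message(sprintf("[%s] %s: %s", format(Sys.time(), "%H:%M:%S"),
                    stage, sprintf(fmt, ...)))
}

#' Run the full two-stage feature-selection pipeline
#'
#' Executes, in order: constant-feature removal, stage-stratified
#' irrelevance screening, class- and covariate-balanced representative
#' sampling, consensus rank selection, KL-NMF at the chosen rank,
#' basis-row similarity, redundant-group inference, mixed-feature
#' compression of the full relevant dataset, and (optionally) LS-SVM
#' scoring of the selected subset against the untransformed relevant
#' feature set on the representative samples. Every stage derives its own
#' seed from the master seed, and all artifacts are written under
#' `cfg$out_dir` when set, stamped with the config hash.
#'
#' @param ds a [clinical_dataset()] or a path readable by
#'   [read_dataset()].
#' @param cfg a [pipeline_config()].
#' @param verbose log one line per stage (default FALSE).
#' @return a `pipeline_result` with elements `constant_removed`,
#'   `freq_table`, `irrelevant`, `relevant_ds`, `representatives`,
#'   `rank_survey`, `fit`, `similarity`, `basis_of`, `groups`, `subset`,
#'   `validation` (subset and full-set accuracy summaries, or `NULL`),
#'   `config`, `config_hash`.
#' @export
run_pipeline <- function(ds, cfg = pipeline_config(), verbose = FALSE) {
  stopifnot(inherits(cfg, "pipeline_config"))
  if (is.character(ds)) ds <- read_dataset(ds)
  stopifnot(inherits(ds, "clinical_dataset"))
  hash <- config_hash(cfg)
  seeds <- ns_derive_seeds(cfg$seed, 4L)  # rank, nmf(unused spare), mix, cv

  step <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop(errorCondition(
        sprintf("pipeline stage `%s` failed: %s", stage, conditionMessage(e)),
        class = c("ns_pipeline_error", class(e))))
    })
  }

  dropped <- step("preprocess", drop_constant_features(ds))
  pipeline_log(verbose, "preprocess", "%d constant symptom(s) removed",
               length(dropped$removed))

  ft <- step("screening", positive_frequencies(dropped$dataset,
                                               cfg$stratify_by))
  irrelevant <- step("screening", find_irrelevant(ft, cfg$freq_threshold))
  relevant <- step("screening",
                   if (length(irrelevant))
                     remove_features(dropped$dataset, irrelevant)
                   else dropped$dataset)
  pipeline_log(verbose, "screening", "%d irrelevant of %d symptoms removed",
               length(irrelevant), n_symptoms(dropped$dataset))

  reps <- step("sampling",
               select_representatives(relevant, cfg$per_class,
                                      cfg$balance, cfg$ratio))
  X <- t(reps$dataset$values)  # NMF treats features as rows
  pipeline_log(verbose, "sampling", "representative matrix %d x %d",
               nrow(X), ncol(X))

  survey <- step("rank_selection",
                 select_rank(X, cfg$rank_range, cfg$nmf, cfg$n_runs,
                             seed = seeds[1L]))
  r <- survey$selected
  fit <- survey$best_fits[[as.character(r)]]
  pipeline_log(verbose, "rank_selection", "rank %d (rule: %s)", r,
               survey$rule)

  sims <- step("similarity", similarity_matrices(fit$W))
  basis_of <- assign_feature_basis(fit$W)
  groups <- step("grouping",
                 find_redundant_groups(sims, basis_of, cfg$theta,
                                       cfg$rule, cfg$same_basis))
  pipeline_log(verbose, "grouping", "%d redundant group(s)",
               length(groups$groups))

  subset <- step("transform",
                 assemble_subset(relevant, groups, cfg$strategy,
                                 seed = seeds[3L]))
  pipeline_log(verbose, "transform", "%d features (%d kept + %d mixed)",
               length(subset$feature_ids), length(subset$kept),
               length(subset$mixed))

  validation <- NULL
  if (isTRUE(cfg$validate)) {
    train <- reps$dataset
    validation <- step("validation", list(
      subset = evaluate_subset(train, subset = subset,
                               a_range = cfg$a_range, b_range = cfg$b_range,
                               folds = cfg$folds, seed = seeds[4L]),
      full = evaluate_subset(train, subset = NULL,
                             a_range = cfg$a_range, b_range = cfg$b_range,
                             folds = cfg$folds, seed = seeds[4L])
    ))
    pipeline_log(verbose, "validation",
                 "CV accuracy %.3f (subset) vs %.3f (all features)",
                 validation$subset$cv_mean, validation$full$cv_mean)
  }

  result <- structure(
    list(constant_removed = dropped$removed, freq_table = ft,
         irrelevant = irrelevant, relevant_ds = relevant,
         representatives = reps, rank_survey = survey, fit = fit,
         similarity = sims, basis_of = basis_of, groups = groups,
         subset = subset, validation = validation, config = cfg,
         config_hash = hash),
    class = "pipeline_result")
  if (!is.null(cfg$out_dir)) write_pipeline_artifacts(result, cfg$out_dir)
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  cat(sprintf("  irrelevant removed: %d (%s)\n", length(x$irrelevant),
              paste(x$irrelevant, collapse = ", ")))
  cat(sprintf("  selected rank: %d (rule: %s)\n", x$rank_survey$selected,
              x$rank_survey$rule))
  cat(sprintf("  redundant groups: %d covering %d symptoms\n",
              length(x$groups$groups),
              length(unlist(lapply(x$groups$groups, `[[`, "members")))))
  cat(sprintf("  selected subset: %d features (%d original + %d mixed)\n",
              length(x$subset$feature_ids), length(x$subset$kept),
              length(x$subset$mixed)))
  if (!is.null(x$validation))
    cat(sprintf("  CV accuracy: %.4f +/- %.4f (subset) vs %.4f +/- %.4f (all)\n",
                x$validation$subset$cv_mean, x$validation$subset$cv_sd,
                x$validation$full$cv_mean, x$validation$full$cv_sd))
  cat(sprintf("  config hash: %s\n", x$config_hash))
  invisible(x)
}

write_tsv_stamped <- function(df, path, hash) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# config_hash: ", hash), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write every pipeline artifact to a directory
#'
#' Emits TSV diagnostics (frequencies, rank survey, W, H, similarity
#' matrices, grid report), the JSON group report, the transformed dataset,
#' and a JSON run summary; each TSV carries the config hash as a comment
#' line.
#'
#' @param result a [run_pipeline()] result.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_pipeline_artifacts <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  h <- result$config_hash
  ft <- result$freq_table
  write_tsv_stamped(data.frame(symptom = rownames(ft$freq), ft$freq,
                               check.names = FALSE),
                    file.path(dir, "frequencies.tsv"), h)
  write_tsv_stamped(data.frame(rank = result$rank_survey$ranks,
                               cophenetic = result$rank_survey$cophenetic,
                               rss = result$rank_survey$rss),
                    file.path(dir, "rank_survey.tsv"), h)
  write_tsv_stamped(data.frame(symptom = rownames(result$fit$W),
                               result$fit$W, check.names = FALSE),
                    file.path(dir, "W.tsv"), h)
  write_tsv_stamped(data.frame(basis = rownames(result$fit$H),
                               result$fit$H, check.names = FALSE),
                    file.path(dir, "H.tsv"), h)
  for (nm in c("sim_dist", "sim_corr", "smx"))
    write_tsv_stamped(data.frame(symptom = rownames(result$similarity[[nm]]),
                                 result$similarity[[nm]],
                                 check.names = FALSE),
                      file.path(dir, paste0(nm, ".tsv")), h)
  write_groups(result$groups, file.path(dir, "groups.json"))
  write_tsv_stamped(data.frame(sample_id = rownames(result$subset$values),
                               stage = result$subset$stage,
                               result$subset$values, check.names = FALSE),
                    file.path(dir, "transformed.tsv"), h)
  if (!is.null(result$validation))
    write_tsv_stamped(result$validation$subset$grid$grid,
                      file.path(dir, "grid_subset.tsv"), h)
  summary <- list(
    config_hash = h,
    constant_removed = result$constant_removed,
    irrelevant = result$irrelevant,
    selected_rank = result$rank_survey$selected,
    rank_rule = result$rank_survey$rule,
    groups = lapply(result$groups$groups, `[[`, "members"),
    n_features = length(result$subset$feature_ids),
    kept = result$subset$kept,
    mixed = vapply(result$subset$mixed, `[[`, character(1), "id"),
    cv_subset = if (!is.null(result$validation))
      c(mean = result$validation$subset$cv_mean,
        sd = result$validation$subset$cv_sd),
    cv_full = if (!is.null(result$validation))
      c(mean = result$validation$full$cv_mean,
        sd = result$validation$full$cv_sd))
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
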