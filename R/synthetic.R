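#' Specification for a synthetic clinical symptom dataset
#'
#' Describes a three-stage questionnaire-style cohort with known ground
#' truth: informative symptoms whose positive probability is elevated in
#' one "affinity" stage, planted irrelevant symptoms that are rarely
#' positive in every stage, and planted redundant groups whose members are
#' noisy copies of one source column. The defaults reproduce the shape of
#' a 407-patient hepatocellular-carcinoma cohort: stage sizes 82/195/130,
#' substage A fractions and male fractions chosen so that rounding gives
#' the tabulated substage counts (45/37, 60/135, 111/19) and male counts
#' (60/165/105), 57 symptoms of which 8 are irrelevant and 16 sit in 6
#' redundant groups of sizes 3, 2, 2, 5, 2, 2.
#'
#' @param n_per_stage samples per stage.
#' @param substage_frac_a fraction of each stage in the "A" substage.
#' @param male_frac male fraction per stage (sex coded `"M"`/`"F"`).
#' @param n_informative standalone informative symptoms.
#' @param n_irrelevant planted irrelevant symptoms.
#' @param group_sizes sizes (>= 2) of the planted redundant groups; each
#'   group is one source pattern plus noisy copies.
#' @param max_level maximum ordinal severity level L for non-binary
#'   symptoms (values lie in 0..L).
#' @param binary_frac fraction of informative symptoms that are binary.
#' @param peak_range range of the positive probability in a symptom's
#'   affinity stage; drawn log-uniformly so low-frequency symptoms are as
#'   common as high-frequency ones, emulating the wide spread (a few
#'   percent to over half the cohort) seen in questionnaire data.
#' @param background_rel_range relative positive probability in the other
#'   stages, as a fraction of the peak.
#' @param p_irrelevant_range per-stage positive-probability range for
#'   irrelevant symptoms (kept below 0.10 minus a margin).
#' @param flip_noise per-entry probability that a redundant copy is
#'   perturbed one severity level up or down (clipped to `[0, L]`).
#' @param severity_decay geometric decay of severity levels given
#'   positivity.
#' @param burden_sd log-normal sigma of the per-patient overall symptom
#'   burden. Patients differ in how many symptoms they present beyond
#'   what their stage implies; symptoms load on this burden with
#'   different strengths, which gives the data the within-stage
#'   co-variation real questionnaires show (a purely
#'   stage-conditionally-independent matrix is exactly low-rank, a
#'   degenerate geometry in which basis rows of unrelated symptoms
#'   collapse onto common rays).
#' @param burden_load_range per-symptom exponent range on the burden
#'   (shared by all members of a redundant group via the copied values).
#' @param sep_corr,sep_dist_frac identifiability margin of the planted
#'   ground truth: any two distinct same-stage symptom patterns must
#'   differ either by expected-profile correlation below `sep_corr` or by
#'   squared profile distance of at least `sep_dist_frac` of the largest
#'   possible pairwise distance (rejection sampling). Without such a
#'   margin "redundant" would be ill-defined: rank-limited basis rows
#'   cannot separate arbitrarily similar unplanted patterns.
#' @param seed RNG seed; generation is fully deterministic given the spec.
#' @return a `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_per_stage = c(82L, 195L, 130L),
                           substage_frac_a = c(45 / 82, 60 / 195, 111 / 130),
                           male_frac = c(60 / 82, 165 / 195, 105 / 130),
                           n_informative = 33L,
                           n_irrelevant = 8L,
                           group_sizes = c(3L, 2L, 2L, 5L, 2L, 2L),
                           max_level = 3L,
                           binary_frac = 0.4,
                           peak_range = c(0.2, 0.85),
                           background_rel_range = c(0, 0.8),
                           p_irrelevant_range = c(0.01, 0.05),
                           flip_noise = 0.02,
                           severity_decay = 0.5,
                           burden_sd = 0.4,
                           burden_load_range = c(0.3, 1.7),
                           sep_corr = 0.93,
                           sep_dist_frac = 0.07,
                           seed = 1L) {
  spec <- list(n_per_stage = as.integer(n_per_stage),
               substage_frac_a = substage_frac_a,
               male_frac = male_frac,
               n_informative = as.integer(n_informative),
               n_irrelevant = as.integer(n_irrelevant),
               group_sizes = as.integer(group_sizes),
               max_level = as.integer(max_level),
               binary_frac = binary_frac,
               peak_range = peak_range,
               background_rel_range = background_rel_range,
               p_irrelevant_range = p_irrelevant_range,
               flip_noise = flip_noise,
               severity_decay = severity_decay,
               burden_sd = burden_sd,
               burden_load_range = burden_load_range,
               sep_corr = sep_corr,
               sep_dist_frac = sep_dist_frac,
               seed = as.integer(seed))
  probs <- c(spec$substage_frac_a, spec$male_frac, spec$binary_frac,
             spec$peak_range, spec$background_rel_range,
             spec$p_irrelevant_range, spec$flip_noise, spec$severity_decay)
  if (any(probs < 0 | probs > 1))
    ns_abort("all probabilities must lie in [0, 1]", "ns_validation_error")
  if (length(spec$n_per_stage) != 3L || any(spec$n_per_stage < 1L))
    ns_abort("`n_per_stage` must give three positive counts",
             "ns_validation_error")
  if (length(spec$group_sizes) && any(spec$group_sizes < 2L))
    ns_abort("every redundant group needs size >= 2", "ns_validation_error")
  if (spec$max_level < 1L)
    ns_abort("`max_level` must be >= 1", "ns_validation_error")
  if (spec$n_informative < length(spec$group_sizes))
    ns_abort("not enough informative patterns to seed the groups",
             "ns_validation_error")
  structure(spec, class = "synthetic_spec")
}

#' Preset reproducing the tabulated cohort shape
#'
#' A [synthetic_spec()] whose defaults already encode the 407 x 57 cohort
#' (stage sizes 82/195/130, 8 planted irrelevant symptoms, 6 planted
#' redundant groups covering 16 symptoms, substage and sex imbalance as
#' tabulated).
#'
#' @param seed RNG seed.
#' @return a `synthetic_spec`.
#' @export
hcc_preset <- function(seed = 1L) {
  synthetic_spec(seed = seed)
}

# Truncated-geometric severity draw on 1..L given positivity.
draw_severity <- function(n, L, decay) {
  if (L == 1L) return(rep(1L, n))
  probs <- decay^(seq_len(L) - 1L)
  sample.int(L, n, replace = TRUE, prob = probs / sum(probs))
}

#' Generate a synthetic clinical dataset with known ground truth
#'
#' Samples a [clinical_dataset()] according to the spec. Symptom columns
#' are assigned to roles (standalone informative, redundant-group member,
#' irrelevant) in a seeded random order; substage and sex labels are
#' assigned by exact rounded counts so the cohort composition is fixed,
#' not resampled. Redundant-group members are copies of their source
#' column, each entry independently perturbed one severity level up or
#' down with probability `flip_noise` and clipped to the valid range.
#'
#' @param spec a [synthetic_spec()].
#' @return list with `dataset` (a `clinical_dataset`) and `truth`: the
#'   planted `irrelevant` ids, `groups` (list of member-id vectors, source
#'   first), and `signature` (affinity stage per informative symptom id).
#' @export
generate_clinical <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  ns_with_seed(spec$seed, {
    n_groups <- length(spec$group_sizes)
    n_sym <- spec$n_informative + sum(spec$group_sizes) + spec$n_irrelevant
    p <- sum(spec$n_per_stage)

    # sample labels: exact counts per stage/substage/sex
    stage <- rep(1:3, spec$n_per_stage)
    substage <- character(p)
    sex <- character(p)
    roman <- c("I", "II", "III")
    for (s in 1:3) {
      idx <- which(stage == s)
      n_a <- round(spec$substage_frac_a[s] * length(idx))
      substage[idx] <- rep(c(paste0(roman[s], "A"), paste0(roman[s], "B")),
                           c(n_a, length(idx) - n_a))
      n_m <- round(spec$male_frac[s] * length(idx))
      sex[idx] <- sample(rep(c("M", "F"), c(n_m, length(idx) - n_m)))
    }

    # per-pattern parameters for informative symptoms; the first n_groups
    # patterns seed the redundant groups, two affinity stages per basis
    n_patterns <- spec$n_informative + n_groups
    affinity <- c(rep_len(1:3, n_groups),
                  rep_len(1:3, spec$n_informative))
    sev_mean <- function(L) {
      pr <- spec$severity_decay^(seq_len(L) - 1L)
      sum(seq_len(L) * pr) / sum(pr)
    }
    # largest achievable expected-profile norm, for the distance margin
    m_max <- spec$peak_range[2] * sev_mean(spec$max_level) *
      sqrt(1 + 2 * spec$background_rel_range[2]^2)
    sep_d2 <- spec$sep_dist_frac * 2 * m_max^2

    L <- integer(n_patterns)
    p_pos <- matrix(0, n_patterns, 3)
    profiles <- matrix(0, n_patterns, 3)  # expected W-scale profiles
    for (k in seq_len(n_patterns)) {
      for (try in seq_len(500L)) {
        L_k <- if (stats::runif(1) < spec$binary_frac) 1L else spec$max_level
        peak <- exp(stats::runif(1, log(spec$peak_range[1]),
                                 log(spec$peak_range[2])))
        pp <- peak * stats::runif(3, spec$background_rel_range[1],
                                  spec$background_rel_range[2])
        pp[affinity[k]] <- peak
        prof <- pp * sev_mean(L_k)
        # enforce the identifiability margin against same-stage patterns
        prior <- which(seq_len(k - 1L) > 0 &
                         affinity[seq_len(k - 1L)] == affinity[k])
        ok <- TRUE
        for (j in prior) {
          close_angle <- stats::cor(prof, profiles[j, ]) > spec$sep_corr
          close_dist <- sum((prof - profiles[j, ])^2) < sep_d2
          if (close_angle && close_dist) { ok <- FALSE; break }
        }
        if (ok || try == 500L) {
          L[k] <- L_k; p_pos[k, ] <- pp; profiles[k, ] <- prof
          break
        }
      }
    }

    # per-patient overall symptom burden and per-symptom loading on it:
    # positivity probability 1 - (1 - p)^(t^lambda), i.e. burden acts as
    # an exposure multiplier
    burden <- stats::rlnorm(p, 0, spec$burden_sd)
    load <- stats::runif(n_patterns, spec$burden_load_range[1],
                         spec$burden_load_range[2])
    draw_column <- function(k) {
      v <- integer(p)
      expo <- burden^load[k]
      for (s in 1:3) {
        idx <- which(stage == s)
        q <- 1 - (1 - p_pos[k, s])^expo[idx]
        pos <- stats::runif(length(idx)) < q
        v[idx[pos]] <- draw_severity(sum(pos), L[k], spec$severity_decay)
      }
      v
    }

    perturb <- function(v, L) {
      hit <- which(stats::runif(length(v)) < spec$flip_noise)
      if (length(hit)) {
        step <- sample(c(-1L, 1L), length(hit), replace = TRUE)
        v[hit] <- pmin(pmax(v[hit] + step, 0L), L)
      }
      v
    }

    # build columns: group sources + copies, standalone informative,
    # irrelevant
    cols <- list()
    roles <- character(0)
    group_of <- integer(0)
    for (g in seq_len(n_groups)) {
      src <- draw_column(g)
      cols <- c(cols, list(src))
      roles <- c(roles, "group"); group_of <- c(group_of, g)
      for (cp in seq_len(spec$group_sizes[g] - 1L)) {
        cols <- c(cols, list(perturb(src, L[g])))
        roles <- c(roles, "group"); group_of <- c(group_of, g)
      }
    }
    for (k in seq_len(spec$n_informative)) {
      cols <- c(cols, list(draw_column(n_groups + k)))
      roles <- c(roles, "informative"); group_of <- c(group_of, 0L)
    }
    for (k in seq_len(spec$n_irrelevant)) {
      p_irr <- stats::runif(3, spec$p_irrelevant_range[1],
                            spec$p_irrelevant_range[2])
      v <- integer(p)
      for (s in 1:3) {
        idx <- which(stage == s)
        pos <- stats::runif(length(idx)) < p_irr[s]
        v[idx[pos]] <- draw_severity(sum(pos), spec$max_level,
                                     spec$severity_decay)
      }
      cols <- c(cols, list(v))
      roles <- c(roles, "irrelevant"); group_of <- c(group_of, 0L)
    }

    # scatter the roles over the symptom index as in a real questionnaire
    perm <- sample.int(n_sym)
    values <- do.call(cbind, cols)[, perm, drop = FALSE]
    roles <- roles[perm]; group_of <- group_of[perm]
    symptom_ids <- paste0("V", seq_len(n_sym))
    sample_ids <- sprintf("S%03d", seq_len(p))
    colnames(values) <- symptom_ids

    ds <- clinical_dataset(values, symptom_ids, sample_ids,
                           substage = substage, sex = sex)
    # affinity stage per column in pre-permutation order (group members
    # inherit their source's stage; irrelevant symptoms have none)
    aff_by_col <- c(rep(affinity[seq_len(n_groups)], spec$group_sizes),
                    affinity[n_groups + seq_len(spec$n_informative)],
                    rep(NA_integer_, spec$n_irrelevant))
    truth <- list(
      irrelevant = symptom_ids[roles == "irrelevant"],
      groups = lapply(seq_len(n_groups), function(g)
        symptom_ids[group_of == g]),
      signature = stats::setNames(aff_by_col[perm], symptom_ids)
    )
    list(dataset = ds, truth = truth)
  })
}
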