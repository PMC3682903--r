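# Synthetic EMR cohort generator: draws (confirmation class, criterion
# pattern) per patient from a configurable joint, then materializes event
# records exactly as the fixture builder does. Defaults emulate the
# reference L88 cohort: 219 patients, P(confirmed) = 155/219, pattern
# probabilities from the published joint, 64% female, age mean 58 / SD 15.

default_pattern_probabilities <- function() {
  joint <- reconstruct_joint(read_marginal_table())
  split_p <- function(conf_flag) {
    n <- joint$n[joint$confirmed == conf_flag]
    stats::setNames(n / sum(n),
                    pattern_label(joint$c1, joint$c2,
                                  joint$c3)[joint$confirmed == conf_flag])
  }
  list(confirmed = split_p(TRUE), not_confirmed = split_p(FALSE))
}

#' Configuration for the synthetic cohort generator
#'
#' @param n_patients number of patients to generate.
#' @param class_probability probability that a patient's diagnosis is
#'   confirmed at chart review (default 155/219).
#' @param pattern_probabilities list with numeric vectors `confirmed` and
#'   `not_confirmed`, each of length 8 summing to 1: the criterion-pattern
#'   distribution within each class, in [criterion_patterns()] order
#'   (`000` ... `111`). Default: the published joint, normalized per class.
#' @param pct_female fraction of female patients.
#' @param age_mean,age_sd target marginal mean and SD of age at first
#'   index contact, in years.
#' @param seed integer seed; the generator uses one private random stream.
#' @param mode `"exact"`: cell counts are the largest-remainder rounding of
#'   their expectations and the sex split is apportioned exactly (an
#'   n-patient cohort whose composition is deterministic given the seed);
#'   `"stochastic"`: classes, patterns, sexes drawn i.i.d.
#' @return an `ia_generator_config`.
#' @export
generator_config <- function(n_patients = 219,
                             class_probability = 155 / 219,
                             pattern_probabilities =
                               default_pattern_probabilities(),
                             pct_female = 0.64, age_mean = 58, age_sd = 15,
                             seed = 1L,
                             mode = c("exact", "stochastic")) {
  mode <- match.arg(mode)
  if (n_patients < 1) {
    ia_abort("n_patients must be positive", "ia_config_error")
  }
  if (class_probability < 0 || class_probability > 1 ||
      pct_female < 0 || pct_female > 1) {
    ia_abort("probabilities must lie in [0, 1]", "ia_config_error")
  }
  if (age_sd <= 0) {
    ia_abort("age_sd must be positive", "ia_config_error")
  }
  for (cls in c("confirmed", "not_confirmed")) {
    p <- pattern_probabilities[[cls]]
    if (is.null(p) || length(p) != 8 || any(p < 0) ||
        abs(sum(p) - 1) > 1e-9) {
      ia_abort(sprintf(
        "pattern_probabilities$%s must be 8 non-negative values summing to 1",
        cls), "ia_config_error")
    }
  }
  structure(list(n_patients = as.integer(n_patients),
                 class_probability = class_probability,
                 pattern_probabilities = pattern_probabilities,
                 pct_female = pct_female, age_mean = age_mean,
                 age_sd = age_sd, seed = as.integer(seed), mode = mode),
            class = "ia_generator_config")
}

#' Generate a synthetic EMR cohort
#'
#' In `"exact"` mode the 16 cell counts (class x pattern) are the
#' largest-remainder apportionment of `n_patients` over the configured
#' cell probabilities; with the default configuration and `n_patients =
#' 219` every expectation is an exact integer, so the generated cohort
#' reproduces the published joint -- and hence the published validation
#' table -- exactly. In `"stochastic"` mode each patient's class and
#' pattern are drawn independently. Identical configurations (including
#' the seed) yield byte-identical cohorts.
#'
#' @param config an [generator_config()].
#' @return an `ia_cohort`; every generated patient passes
#'   [select_cohort()] and realizes exactly its drawn criterion pattern
#'   under [extract_profiles()].
#' @export
generate_cohort <- function(config = generator_config()) {
  stopifnot(inherits(config, "ia_generator_config"))
  pat <- criterion_patterns()
  cell_probs <- c(config$class_probability *
                    config$pattern_probabilities$confirmed,
                  (1 - config$class_probability) *
                    config$pattern_probabilities$not_confirmed)
  withr::with_seed(config$seed, {
    if (config$mode == "exact") {
      counts <- largest_remainder(cell_probs, config$n_patients)
      joint <- new_joint(tibble(
        confirmed = rep(c(TRUE, FALSE), each = 8),
        dplyr::bind_rows(pat, pat), n = counts))
      assign <- expand_joint(joint)
    } else {
      confirmed <- runif(config$n_patients) < config$class_probability
      pattern_idx <- integer(config$n_patients)
      for (cls in c(TRUE, FALSE)) {
        p <- if (cls) config$pattern_probabilities$confirmed else
          config$pattern_probabilities$not_confirmed
        k <- sum(confirmed == cls)
        if (k > 0) {
          pattern_idx[confirmed == cls] <-
            sample.int(8, k, replace = TRUE, prob = p)
        }
      }
      assign <- tibble(confirmed = confirmed,
                       c1 = pat$c1[pattern_idx],
                       c2 = pat$c2[pattern_idx],
                       c3 = pat$c3[pattern_idx])
    }
    build_patient_tables(
      assign, pct_female = config$pct_female, age_mean = config$age_mean,
      age_sd = config$age_sd,
      demographics = if (config$mode == "exact") "apportioned" else "sampled")
  })
}
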