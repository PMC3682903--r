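# The three case-finding criteria over an L88-coded cohort:
#   1. a repeat prescription for a DMARD or biological agent (issued without
#      a consultation -- the GP continuing specialist-initiated therapy);
#   2. at least four index-coded contacts OR one index-coded episode,
#      combined with at least two prescriptions linked to the index code
#      (DMARDs/biologicals excluded from that count);
#   3. age at the first index-coded event between min_age and the age
#      cut-off (default 30-61 years), inclusive on both ends.
# Criterion 1 deliberately requires no index-code link on the DMARD
# prescription: specialists initiate DMARDs without a GP-coded indication.

#' DMARD / biological-agent medication catalog
#'
#' ATC prefixes identifying disease-modifying antirheumatic drugs and
#' biological agents. The defaults are the standard pharmacoepidemiological
#' mapping: L04A (immunosuppressants including biologicals), L01BA01
#' (methotrexate), P01BA02 (hydroxychloroquine), A07EC01 (sulfasalazine),
#' M01CB (gold salts), M01CC01 (penicillamine).
#'
#' @param prefixes character vector of ATC code prefixes.
#' @return an `ia_catalog` object.
#' @export
medication_catalog <- function(prefixes = c("L04A", "L01BA01", "P01BA02",
                                            "A07EC01", "M01CB", "M01CC01")) {
  prefixes <- unique(toupper(trimws(prefixes)))
  if (length(prefixes) == 0 || any(prefixes == "") ||
      any(!grepl("^[A-Z][0-9A-Z]*$", prefixes))) {
    ia_abort("catalog needs at least one valid ATC prefix",
             "ia_config_error")
  }
  structure(list(dmard_biologic_atc_prefixes = prefixes),
            class = "ia_catalog")
}

#' Extract per-patient criterion profiles
#'
#' Computes, for every patient of an already-selected cohort, the feature
#' fields the three criteria read (index-coded contact count, episode flag,
#' count of index-linked non-DMARD prescriptions, repeat-DMARD flag, age at
#' first index event), the criterion booleans `c1`..`c3`, and the
#' chart-review confirmation recomputed from the stored term set.
#'
#' @param x an `ia_cohort` whose patients all carry an index-coded event
#'   (i.e. the output of [select_cohort()]).
#' @param index_code ICPC-1 rubric, default `"L88"`.
#' @param catalog a [medication_catalog()].
#' @param age_cutoff inclusive upper age bound for criterion 3 (years).
#' @param min_age inclusive lower age bound for criterion 3 (years).
#' @param vocab a [confirmation_vocabulary()].
#' @return tibble with one row per patient: `patient_id`, `sex`,
#'   `n_l88_contacts`, `has_l88_episode`, `n_l88_linked_rx_non_dmard`,
#'   `has_repeat_dmard`, `age_at_first_l88`, `c1`, `c2`, `c3`, `confirmed`.
#' @export
extract_profiles <- function(x, index_code = "L88",
                             catalog = medication_catalog(),
                             age_cutoff = 61, min_age = 30,
                             vocab = confirmation_vocabulary()) {
  stopifnot(inherits(x, "ia_cohort"), inherits(catalog, "ia_catalog"))
  idx <- first_index_event(x, index_code)
  if (any(is.na(idx$index_date))) {
    ia_abort(
      sprintf("patient(s) without an index-coded event: %s",
              paste(idx$patient_id[is.na(idx$index_date)], collapse = ", ")),
      "ia_domain_error"
    )
  }

  con <- dplyr::count(
    dplyr::filter(x$contacts, icpc_matches(.data$icpc_code, index_code)),
    .data$patient_id, name = "n_l88_contacts")
  epi <- dplyr::distinct(
    dplyr::transmute(
      dplyr::filter(x$episodes, icpc_matches(.data$icpc_code, index_code)),
      patient_id = .data$patient_id, has_l88_episode = TRUE))
  rx <- x$prescriptions
  linked_non_dmard <- !is.na(rx$linked_icpc_code) &
    icpc_matches(rx$linked_icpc_code, index_code) &
    !atc_in_catalog(rx$atc_code, catalog)
  rx_n <- dplyr::count(rx[linked_non_dmard, ], .data$patient_id,
                       name = "n_l88_linked_rx_non_dmard")
  repeat_dmard <- dplyr::distinct(
    dplyr::transmute(
      rx[rx$is_repeat & atc_in_catalog(rx$atc_code, catalog), ],
      patient_id = .data$patient_id, has_repeat_dmard = TRUE))

  prof <- dplyr::select(x$patients, "patient_id", "sex", "birth_date",
                        "specialist_terms")
  prof <- Reduce(function(a, b) dplyr::left_join(a, b, by = "patient_id"),
                 list(prof, con, epi, rx_n, repeat_dmard, idx))
  prof$n_l88_contacts <- as.integer(dplyr::coalesce(prof$n_l88_contacts, 0L))
  prof$has_l88_episode <- dplyr::coalesce(prof$has_l88_episode, FALSE)
  prof$n_l88_linked_rx_non_dmard <-
    as.integer(dplyr::coalesce(prof$n_l88_linked_rx_non_dmard, 0L))
  prof$has_repeat_dmard <- dplyr::coalesce(prof$has_repeat_dmard, FALSE)
  prof$age_at_first_l88 <- age_at(prof$birth_date, prof$index_date)
  prof$confirmed <- vapply(prof$specialist_terms, confirm_ia, logical(1),
                           vocab = vocab)
  prof$c1 <- criterion1(prof)
  prof$c2 <- criterion2(prof)
  prof$c3 <- criterion3(prof, age_cutoff = age_cutoff, min_age = min_age)
  dplyr::select(prof, "patient_id", "sex", "n_l88_contacts",
                "has_l88_episode", "n_l88_linked_rx_non_dmard",
                "has_repeat_dmard", "age_at_first_l88",
                "c1", "c2", "c3", "confirmed")
}

#' Criterion 1: repeat DMARD/biologic prescription
#' @param profiles a profile tibble (see [extract_profiles()]).
#' @return logical vector, one element per patient.
#' @export
criterion1 <- function(profiles) {
  profiles$has_repeat_dmard
}

#' Criterion 2: index-coded contact volume plus linked prescriptions
#'
#' At least four index-coded contacts or one index-coded episode, combined
#' with at least two index-linked prescriptions other than
#' DMARDs/biologicals.
#' @inheritParams criterion1
#' @return logical vector.
#' @export
criterion2 <- function(profiles) {
  (profiles$n_l88_contacts >= 4 | profiles$has_l88_episode) &
    profiles$n_l88_linked_rx_non_dmard >= 2
}

#' Criterion 3: age band at first index-coded event
#'
#' Age between `min_age` and `age_cutoff` inclusive. The default cut-off of
#' 61 years is the cohort's mean age at diagnosis; patients first coded
#' above it are more likely to carry another diagnosis such as
#' osteoarthritis.
#' @inheritParams criterion1
#' @param age_cutoff inclusive upper bound (years).
#' @param min_age inclusive lower bound (years).
#' @return logical vector.
#' @export
criterion3 <- function(profiles, age_cutoff = 61, min_age = 30) {
  profiles$age_at_first_l88 >= min_age &
    profiles$age_at_first_l88 <= age_cutoff
}

#' Define a k-of-n selection rule over the three criteria
#'
#' @param criteria subset of `c(1, 2, 3)`: which criteria participate.
#' @param min_satisfied how many of them a patient must satisfy (at least).
#' @return an `ia_algorithm_spec`.
#' @examples
#' algorithm_spec(c(1, 2, 3), 1)  # "at least one of the three"
#' @export
algorithm_spec <- function(criteria, min_satisfied = 1) {
  criteria <- sort(unique(as.integer(criteria)))
  if (length(criteria) == 0 || !all(criteria %in% 1:3)) {
    ia_abort("criteria must be a non-empty subset of {1, 2, 3}",
             "ia_config_error")
  }
  min_satisfied <- as.integer(min_satisfied)
  if (is.na(min_satisfied) || min_satisfied < 1 ||
      min_satisfied > length(criteria)) {
    ia_abort("min_satisfied must be between 1 and the number of criteria",
             "ia_config_error")
  }
  structure(list(criteria = criteria, min_satisfied = min_satisfied),
            class = "ia_algorithm_spec")
}

#' @export
format.ia_algorithm_spec <- function(x, ...) {
  sprintf(">=%d of {%s}", x$min_satisfied, paste(x$criteria, collapse = ","))
}

#' @export
print.ia_algorithm_spec <- function(x, ...) {
  cat("<ia_algorithm_spec>", format(x), "\n")
  invisible(x)
}

#' Apply a k-of-n selection rule
#'
#' @param profiles a profile tibble (see [extract_profiles()]).
#' @param spec an [algorithm_spec()].
#' @return character vector of selected `patient_id`s (patients satisfying
#'   at least `min_satisfied` of the spec's criteria).
#' @export
apply_algorithm <- function(profiles, spec) {
  if (!inherits(spec, "ia_algorithm_spec")) {
    ia_abort("spec must be an ia_algorithm_spec", "ia_config_error")
  }
  flags <- as.matrix(profiles[paste0("c", spec$criteria)])
  profiles$patient_id[rowSums(flags) >= spec$min_satisfied]
}
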