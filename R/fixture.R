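# Materializing patient-level records from a joint distribution: one
# patient per unit count, with events constructed so that profile
# extraction reproduces the patient's criterion pattern exactly:
#   c1 TRUE  -> one repeat methotrexate prescription (ATC L01BA01);
#   c2 TRUE  -> four index-coded contacts plus two index-linked NSAID
#               prescriptions (ATC M01AE01, outside the DMARD catalog);
#   c2 FALSE -> a single index-coded contact (every patient must carry at
#               least one index-coded event) and no linked prescriptions;
#   c3       -> birth date placed so the age at the first index contact
#               falls inside (or outside) the 30-61 band.
# Confirmed patients carry the term "rheumatoid arthritis"; the others
# "osteoarthritis" (a coded-but-unconfirmed diagnosis, e.g. an initial
# suspicion later revised).

# Band-conditional age model. Marginal ages are a two-band mixture whose
# parameters are calibrated so that, at the reference criterion-3 mix
# (105/219 inside the band), the marginal mean and SD are ~58 and ~15
# years: inside-band ages ~ N(age_mean - 13, 11 * age_sd / 15) clamped to
# [min_age, age_cutoff]; outside-band ages ~ N(age_mean + 10, 10 *
# age_sd / 15) clamped to [age_cutoff + 1, Inf).
draw_ages <- function(c3, age_mean, age_sd, min_age = 30, age_cutoff = 61) {
  n <- length(c3)
  lo <- round(rnorm(n, age_mean - 13, 11 * age_sd / 15))
  hi <- round(rnorm(n, age_mean + 10, 10 * age_sd / 15))
  ifelse(c3, pmin(pmax(lo, min_age), age_cutoff),
         pmax(hi, age_cutoff + 1))
}

# assign: tibble(confirmed, c1, c2, c3), one row per patient. Consumes the
# active RNG stream; callers wrap in withr::with_seed().
build_patient_tables <- function(assign, index_code = "L88",
                                 window = as.Date(c("2003-01-01",
                                                    "2008-12-31")),
                                 pct_female = 0.64, age_mean = 58,
                                 age_sd = 15,
                                 demographics = c("apportioned", "sampled")) {
  demographics <- match.arg(demographics)
  n <- nrow(assign)
  if (n == 0) {
    return(cohort())
  }
  ids <- sprintf("P%04d", seq_len(n))
  span <- as.integer(window[2] - window[1]) + 1L
  index_date <- window[1] + (sample.int(span, n, replace = TRUE) - 1L)
  age <- draw_ages(assign$c3, age_mean, age_sd)
  # birth 30 days before the index-date anniversary, so the completed age
  # at the index date is exactly `age`
  birth_date <- shift_years(index_date - 30L, -age)
  sex <- if (demographics == "apportioned") {
    n_f <- as.integer(round(pct_female * n))
    sample(rep(c("female", "male"), c(n_f, n - n_f)))
  } else {
    ifelse(runif(n) < pct_female, "female", "male")
  }

  n_contacts <- ifelse(assign$c2, 4L, 1L)
  contact_offsets <- unlist(lapply(n_contacts, function(k) {
    seq(0L, by = 30L, length.out = k)
  }))
  contacts <- tibble(
    patient_id = rep(ids, n_contacts),
    date = rep(index_date, n_contacts) + contact_offsets,
    icpc_code = index_code
  )

  dmard_rx <- tibble(
    patient_id = ids[assign$c1],
    date = index_date[assign$c1] + 14L,
    atc_code = "L01BA01",
    linked_icpc_code = NA_character_,
    is_repeat = TRUE
  )
  linked_ids <- ids[assign$c2]
  linked_rx <- tibble(
    patient_id = rep(linked_ids, each = 2L),
    date = rep(index_date[assign$c2], each = 2L) + c(7L, 45L),
    atc_code = "M01AE01",
    linked_icpc_code = index_code,
    is_repeat = FALSE
  )

  patients <- tibble(
    patient_id = ids,
    sex = sex,
    birth_date = birth_date,
    specialist_terms = lapply(assign$confirmed, function(cf) {
      if (cf) "rheumatoid arthritis" else "osteoarthritis"
    })
  )
  cohort(patients = patients, contacts = contacts,
         prescriptions = dplyr::arrange(
           dplyr::bind_rows(dmard_rx, linked_rx), .data$patient_id,
           .data$date))
}

expand_joint <- function(joint) {
  idx <- rep(seq_len(nrow(joint)), joint$n)
  tibble(confirmed = joint$confirmed[idx], c1 = joint$c1[idx],
         c2 = joint$c2[idx], c3 = joint$c3[idx])
}

#' Materialize a patient-level fixture from a joint distribution
#'
#' Emits exactly one patient record per unit count of the joint, with
#' events constructed so that [extract_profiles()] on the fixture
#' reproduces the joint exactly. Output is deterministic given `seed`.
#'
#' @param joint an `ia_joint` (see [reconstruct_joint()]).
#' @param seed integer seed for the fixture's private random stream (event
#'   dates, demographic jitter).
#' @param index_code ICPC-1 rubric carried by the constructed events.
#' @param window `Date` vector of length 2: the span in which first index
#'   contacts are placed (the observation window).
#' @param pct_female fraction of female patients (apportioned exactly).
#' @param age_mean,age_sd target marginal moments of age at first index
#'   contact, in years.
#' @return an `ia_cohort` with `sum(joint$n)` patients.
#' @export
materialize_fixture <- function(joint, seed = 1L, index_code = "L88",
                                window = as.Date(c("2003-01-01",
                                                   "2008-12-31")),
                                pct_female = 0.64, age_mean = 58,
                                age_sd = 15) {
  stopifnot(inherits(joint, "ia_joint"))
  withr::with_seed(as.integer(seed), {
    build_patient_tables(expand_joint(joint), index_code = index_code,
                         window = window, pct_female = pct_female,
                         age_mean = age_mean, age_sd = age_sd,
                         demographics = "apportioned")
  })
}
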