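# EMR data model: a cohort is four linked tables (patients, contacts,
# episodes, prescriptions) keyed by patient_id. This mirrors how GP
# registration databases export records and keeps the whole cohort
# vectorisable; per-patient views are derived, never stored.

patients_cols <- c("patient_id", "sex", "birth_date", "specialist_terms")
contacts_cols <- c("patient_id", "date", "icpc_code")
episodes_cols <- c("patient_id", "icpc_code", "start_date", "end_date")
prescriptions_cols <- c("patient_id", "date", "atc_code",
                        "linked_icpc_code", "is_repeat")

empty_patients <- function() {
  tibble(patient_id = character(), sex = character(),
         birth_date = as.Date(character()), specialist_terms = list())
}

#' Construct an EMR cohort
#'
#' Bundles the four record tables of a primary-care EMR extract into a
#' validated `ia_cohort` object.
#'
#' @param patients tibble with columns `patient_id`, `sex`
#'   (`"female"`/`"male"`), `birth_date` (`Date`), `specialist_terms`
#'   (list-column of character vectors: the specialist-letter diagnosis terms
#'   found at chart review).
#' @param contacts tibble with `patient_id`, `date` (`Date`), `icpc_code`.
#' @param episodes tibble with `patient_id`, `icpc_code`, `start_date`,
#'   `end_date` (`Date`, end >= start).
#' @param prescriptions tibble with `patient_id`, `date` (`Date`),
#'   `atc_code`, `linked_icpc_code` (`NA` when the prescription carries no
#'   diagnosis link), `is_repeat` (logical: issued without a consultation).
#' @return an `ia_cohort` object.
#' @export
cohort <- function(patients = empty_patients(),
                   contacts = tibble(patient_id = character(),
                                     date = as.Date(character()),
                                     icpc_code = character()),
                   episodes = tibble(patient_id = character(),
                                     icpc_code = character(),
                                     start_date = as.Date(character()),
                                     end_date = as.Date(character())),
                   prescriptions = tibble(patient_id = character(),
                                          date = as.Date(character()),
                                          atc_code = character(),
                                          linked_icpc_code = character(),
                                          is_repeat = logical())) {
  x <- structure(
    list(patients = as_tibble(patients),
         contacts = as_tibble(contacts),
         episodes = as_tibble(episodes),
         prescriptions = as_tibble(prescriptions)),
    class = "ia_cohort"
  )
  validate_cohort(x)
}

validate_cohort <- function(x) {
  req <- list(patients = patients_cols, contacts = contacts_cols,
              episodes = episodes_cols, prescriptions = prescriptions_cols)
  for (tbl in names(req)) {
    missing <- setdiff(req[[tbl]], names(x[[tbl]]))
    if (length(missing) > 0) {
      ia_abort(
        sprintf("missing required column(s) in %s: %s",
                tbl, paste(missing, collapse = ", ")),
        "ia_schema_error"
      )
    }
  }
  ids <- x$patients$patient_id
  if (anyDuplicated(ids)) {
    ia_abort(
      sprintf("duplicate patient_id: %s",
              paste(unique(ids[duplicated(ids)]), collapse = ", ")),
      "ia_integrity_error"
    )
  }
  for (tbl in c("contacts", "episodes", "prescriptions")) {
    unknown <- setdiff(x[[tbl]]$patient_id, ids)
    if (length(unknown) > 0) {
      ia_abort(
        sprintf("%s rows reference unknown patient_id: %s",
                tbl, paste(unknown, collapse = ", ")),
        "ia_integrity_error"
      )
    }
  }
  if (any(!x$patients$sex %in% c("female", "male"))) {
    ia_abort("sex must be 'female' or 'male'", "ia_schema_error")
  }
  if (any(is.na(x$contacts$icpc_code) | trimws(x$contacts$icpc_code) == "")) {
    ia_abort("contact icpc_code must be non-empty", "ia_schema_error")
  }
  if (any(is.na(x$prescriptions$atc_code) |
          trimws(x$prescriptions$atc_code) == "")) {
    ia_abort("prescription atc_code must be non-empty", "ia_schema_error")
  }
  if (any(x$episodes$end_date < x$episodes$start_date)) {
    ia_abort("episode end_date before start_date", "ia_integrity_error")
  }
  births <- stats::setNames(x$patients$birth_date, ids)
  event_dates <- c(
    stats::setNames(x$contacts$date, x$contacts$patient_id),
    stats::setNames(x$episodes$start_date, x$episodes$patient_id),
    stats::setNames(x$prescriptions$date, x$prescriptions$patient_id)
  )
  if (length(event_dates) > 0 &&
      any(event_dates < births[names(event_dates)])) {
    ia_abort("event date precedes patient birth_date", "ia_integrity_error")
  }
  x
}

#' @export
print.ia_cohort <- function(x, ...) {
  cat(sprintf(
    "<ia_cohort> %d patients | %d contacts | %d episodes | %d prescriptions\n",
    nrow(x$patients), nrow(x$contacts), nrow(x$episodes),
    nrow(x$prescriptions)))
  invisible(x)
}

#' Number of patients in a cohort
#' @param x an `ia_cohort`.
#' @return integer count.
#' @export
n_patients <- function(x) {
  stopifnot(inherits(x, "ia_cohort"))
  nrow(x$patients)
}

#' Age in completed years
#'
#' Epidemiological age: the number of whole years elapsed since birth
#' (floor), so the age increments on the birthday itself. Feb 29 birthdays
#' complete their year on Mar 1 in non-leap years.
#'
#' @param birth_date,date `Date` vectors (recycled).
#' @return integer vector of completed years.
#' @examples
#' age_at(as.Date("1950-06-01"), as.Date("2010-05-31"))  # 59
#' age_at(as.Date("1950-06-01"), as.Date("2010-06-01"))  # 60
#' @export
age_at <- function(birth_date, date) {
  birth_date <- as.Date(birth_date)
  date <- as.Date(date)
  if (any(date < birth_date, na.rm = TRUE)) {
    ia_abort("date precedes birth_date", "ia_domain_error")
  }
  years <- as.integer(format(date, "%Y")) - as.integer(format(birth_date, "%Y"))
  pre_birthday <- format(date, "%m-%d") < format(birth_date, "%m-%d")
  as.integer(years - pre_birthday)
}

#' Date of the first index-coded event per patient
#'
#' The index event is the earliest contact or episode start carrying the
#' index rubric; a coded episode qualifies even without a matching contact,
#' since both routes record the diagnosis.
#'
#' @param x an `ia_cohort`.
#' @param index_code ICPC-1 rubric (default `"L88"`, inflammatory
#'   arthritis). Matching is case-insensitive and sub-rubrics (`"L88.01"`)
#'   match their root.
#' @return tibble with `patient_id` and `index_date` (`NA` for patients with
#'   no index-coded event), one row per patient.
#' @export
first_index_event <- function(x, index_code = "L88") {
  stopifnot(inherits(x, "ia_cohort"))
  hits <- dplyr::bind_rows(
    dplyr::select(
      dplyr::filter(x$contacts, icpc_matches(.data$icpc_code, index_code)),
      "patient_id", "date"),
    dplyr::transmute(
      dplyr::filter(x$episodes, icpc_matches(.data$icpc_code, index_code)),
      patient_id = .data$patient_id, date = .data$start_date)
  )
  firsts <- if (nrow(hits) == 0) {
    tibble(patient_id = character(), index_date = as.Date(character()))
  } else {
    dplyr::summarise(dplyr::group_by(hits, .data$patient_id),
                     index_date = min(.data$date), .groups = "drop")
  }
  dplyr::left_join(dplyr::select(x$patients, "patient_id"), firsts,
                   by = "patient_id")
}

#' Select the study cohort
#'
#' Keeps patients ever registered with the index rubric whose age at the
#' first index-coded event is at least `min_age` (the default of 30 excludes
#' juvenile arthritis), then restricts all event tables to the kept
#' patients. Idempotent.
#'
#' @inheritParams first_index_event
#' @param min_age minimum age in completed years at the first index event.
#' @return an `ia_cohort` containing only eligible patients.
#' @export
select_cohort <- function(x, index_code = "L88", min_age = 30) {
  stopifnot(inherits(x, "ia_cohort"), min_age >= 0)
  idx <- first_index_event(x, index_code)
  idx <- dplyr::left_join(idx,
                          dplyr::select(x$patients, "patient_id", "birth_date"),
                          by = "patient_id")
  has_idx <- !is.na(idx$index_date)
  keep_age <- rep(FALSE, nrow(idx))
  keep_age[has_idx] <-
    age_at(idx$birth_date[has_idx], idx$index_date[has_idx]) >= min_age
  keep <- idx$patient_id[has_idx & keep_age]
  cohort(
    patients = dplyr::filter(x$patients, .data$patient_id %in% keep),
    contacts = dplyr::filter(x$contacts, .data$patient_id %in% keep),
    episodes = dplyr::filter(x$episodes, .data$patient_id %in% keep),
    prescriptions = dplyr::filter(x$prescriptions,
                                  .data$patient_id %in% keep)
  )
}
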