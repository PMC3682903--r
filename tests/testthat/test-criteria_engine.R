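# A one-patient cohort with fully controllable events, old enough for the
# default selection and inside the criterion-3 band unless stated.
one_patient <- function(contacts_n = 1, episode = FALSE, linked_rx = 0,
                        repeat_dmard = FALSE, extra_rx = NULL, age = 55) {
  index <- as.Date("2005-06-15")
  contacts <- tibble::tibble(
    patient_id = "P",
    date = index + 30 * (seq_len(contacts_n) - 1),
    icpc_code = "L88"
  )
  episodes <- if (episode) {
    tibble::tibble(patient_id = "P", icpc_code = "L88",
                   start_date = index, end_date = index + 200)
  } else {
    NULL
  }
  rx <- dplyr::bind_rows(
    if (linked_rx > 0) {
      tibble::tibble(patient_id = "P", date = index + seq_len(linked_rx),
                     atc_code = "M01AE01", linked_icpc_code = "L88",
                     is_repeat = FALSE)
    },
    if (repeat_dmard) {
      tibble::tibble(patient_id = "P", date = index + 14,
                     atc_code = "L04AX03", linked_icpc_code = NA_character_,
                     is_repeat = TRUE)
    },
    extra_rx
  )
  args <- list(
    patients = tibble::tibble(
      patient_id = "P", sex = "female",
      birth_date = iavalidate:::shift_years(index - 30, -as.integer(age)),
      specialist_terms = list("rheumatoid arthritis")),
    contacts = contacts
  )
  if (!is.null(episodes)) args$episodes <- episodes
  if (!is.null(rx) && nrow(rx) > 0) args$prescriptions <- rx
  do.call(cohort, args)
}

profile_of <- function(...) {
  extract_profiles(one_patient(...))
}

test_that("criterion 1 needs a repeat prescription with a catalog ATC code", {
  expect_true(profile_of(repeat_dmard = TRUE)$c1)
  # a non-repeat DMARD does not qualify
  non_repeat <- tibble::tibble(patient_id = "P",
                               date = as.Date("2005-07-01"),
                               atc_code = "L04AX03",
                               linked_icpc_code = NA_character_,
                               is_repeat = FALSE)
  expect_false(profile_of(extra_rx = non_repeat)$c1)
  # a repeat NSAID is a catalog miss
  repeat_nsaid <- tibble::tibble(patient_id = "P",
                                 date = as.Date("2005-07-01"),
                                 atc_code = "M01AE01",
                                 linked_icpc_code = NA_character_,
                                 is_repeat = TRUE)
  expect_false(profile_of(extra_rx = repeat_nsaid)$c1)
})

test_that("criterion 2 combines contact volume (or an episode) with linked prescriptions", {
  expect_true(profile_of(contacts_n = 4, linked_rx = 2)$c2)
  expect_true(profile_of(contacts_n = 1, episode = TRUE, linked_rx = 2)$c2)
  expect_false(profile_of(contacts_n = 3, linked_rx = 5)$c2)
  expect_false(profile_of(contacts_n = 4, linked_rx = 1)$c2)
  # linked DMARD prescriptions are excluded from the linked-rx count
  linked_dmard <- tibble::tibble(patient_id = "P",
                                 date = as.Date("2005-07-01") + 0:1,
                                 atc_code = "L01BA01",
                                 linked_icpc_code = "L88",
                                 is_repeat = FALSE)
  expect_false(profile_of(contacts_n = 4, extra_rx = linked_dmard)$c2)
})

test_that("criterion 3 is the inclusive 30-61 age band at first coded contact", {
  expect_true(profile_of(age = 30)$c3)
  expect_true(profile_of(age = 61)$c3)
  expect_false(profile_of(age = 62)$c3)
  expect_false(profile_of(age = 70)$c3)
  p55 <- profile_of(age = 55)
  expect_identical(p55$age_at_first_l88, 55L)
  expect_true(p55$c3)
})

test_that("extract_profiles computes the feature fields it derives the criteria from", {
  p <- profile_of(contacts_n = 4, episode = TRUE, linked_rx = 2,
                  repeat_dmard = TRUE, age = 40)
  expect_identical(p$n_l88_contacts, 4L)
  expect_true(p$has_l88_episode)
  expect_identical(p$n_l88_linked_rx_non_dmard, 2L)
  expect_true(p$has_repeat_dmard)
  expect_true(all(c(p$c1, p$c2, p$c3, p$confirmed)))
  # re-derivability: the stored booleans equal the criterion functions
  # applied to the stored feature fields
  expect_identical(p$c1, criterion1(p))
  expect_identical(p$c2, criterion2(p))
  expect_identical(p$c3, criterion3(p))
})

test_that("profiles are re-derivable on a full generated cohort", {
  prof <- extract_profiles(select_cohort(table1_fixture(seed = 8)))
  expect_identical(prof$c1, criterion1(prof))
  expect_identical(prof$c2, criterion2(prof))
  expect_identical(prof$c3, criterion3(prof))
})

test_that("extract_profiles rejects patients without an index event", {
  coh <- cohort(patients = tibble::tibble(
    patient_id = "Q", sex = "male", birth_date = as.Date("1950-01-01"),
    specialist_terms = list(character())))
  expect_error(extract_profiles(coh), "Q", class = "ia_domain_error")
})

test_that("algorithm_spec validates its selection rule", {
  expect_error(algorithm_spec(integer()), class = "ia_config_error")
  expect_error(algorithm_spec(c(1, 4)), class = "ia_config_error")
  expect_error(algorithm_spec(c(1, 2), 3), class = "ia_config_error")
  expect_error(algorithm_spec(1, 0), class = "ia_config_error")
  expect_error(apply_algorithm(random_profiles(5, 1), list(criteria = 1)),
               class = "ia_config_error")
})

test_that("k-of-n selections nest and reduce to set union / intersection", {
  for (seed in c(11, 12, 13)) {
    prof <- random_profiles(200, seed)
    for (crit in list(1:3, c(1, 2), c(2, 3))) {
      sels <- lapply(seq_along(crit), function(k) {
        apply_algorithm(prof, algorithm_spec(crit, k))
      })
      for (k in seq_along(crit)[-1]) {
        expect_true(all(sels[[k]] %in% sels[[k - 1]]))
      }
    }
    s1 <- apply_algorithm(prof, algorithm_spec(1))
    s2 <- apply_algorithm(prof, algorithm_spec(2))
    expect_setequal(apply_algorithm(prof, algorithm_spec(c(1, 2), 1)),
                    union(s1, s2))
    expect_setequal(apply_algorithm(prof, algorithm_spec(c(1, 2), 2)),
                    intersect(s1, s2))
  }
})

test_that("selection sizes obey inclusion-exclusion on random cohorts", {
  for (seed in 21:26) {
    prof <- random_profiles(150, seed)
    pairs <- list(c(1, 2), c(1, 3), c(2, 3))
    for (pr in pairs) {
      n_union <- length(apply_algorithm(prof, algorithm_spec(pr, 1)))
      n_i <- length(apply_algorithm(prof, algorithm_spec(pr[1])))
      n_j <- length(apply_algorithm(prof, algorithm_spec(pr[2])))
      n_both <- length(apply_algorithm(prof, algorithm_spec(pr, 2)))
      expect_identical(n_union, n_i + n_j - n_both)
    }
  }
})
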