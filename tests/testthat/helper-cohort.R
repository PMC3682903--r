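# Builders shared across test files. Everything is constructed in code;
# no stored fixtures.

# A minimal hand-built cohort: three patients with contrasting event
# histories around the L88 rubric.
toy_cohort <- function() {
  cohort(
    patients = tibble::tibble(
      patient_id = c("A", "B", "C"),
      sex = c("female", "male", "female"),
      birth_date = as.Date(c("1950-06-01", "1980-01-15", "1935-03-02")),
      specialist_terms = list("rheumatoid arthritis", character(),
                              c("gout", "osteoarthritis"))
    ),
    contacts = tibble::tibble(
      patient_id = c("A", "A", "A", "A", "B", "C"),
      date = as.Date(c("2004-03-01", "2002-07-09", "2004-06-01",
                       "2004-09-01", "2005-05-05", "2006-01-10")),
      icpc_code = c("L88", "L88", "L88", "L88", "K86", "L88.01")
    ),
    episodes = tibble::tibble(
      patient_id = "B",
      icpc_code = "L88",
      start_date = as.Date("2003-01-15"),
      end_date = as.Date("2004-02-01")
    ),
    prescriptions = tibble::tibble(
      patient_id = c("A", "A", "A", "C"),
      date = as.Date(c("2002-08-01", "2002-09-01", "2003-01-05",
                       "2006-02-01")),
      atc_code = c("M01AE01", "M01AE01", "L01BA01", "M01AB05"),
      linked_icpc_code = c("L88", "L88", NA, NA),
      is_repeat = c(FALSE, FALSE, TRUE, FALSE)
    )
  )
}

# Random profile tables for algorithm-combinator properties: only the
# columns apply_algorithm() reads.
random_profiles <- function(n, seed) {
  withr::with_seed(seed, tibble::tibble(
    patient_id = sprintf("R%04d", seq_len(n)),
    c1 = stats::runif(n) < 0.3,
    c2 = stats::runif(n) < 0.4,
    c3 = stats::runif(n) < 0.5,
    confirmed = stats::runif(n) < 0.7
  ))
}

# Random non-negative joints for the reconstruction round-trip property.
random_joint <- function(seed, max_count = 30) {
  withr::with_seed(seed, {
    pat <- criterion_patterns()
    iavalidate:::new_joint(tibble::tibble(
      confirmed = rep(c(TRUE, FALSE), each = 8),
      dplyr::bind_rows(pat, pat),
      n = sample(0:max_count, 16, replace = TRUE)
    ))
  })
}

# Independent brute-force oracle for k-of-n selection: per-criterion id
# sets plus explicit membership counting, no matrix arithmetic.
brute_select <- function(profiles, criteria, k) {
  sets <- lapply(criteria, function(i) {
    profiles$patient_id[profiles[[paste0("c", i)]]]
  })
  hits <- vapply(profiles$patient_id, function(id) {
    sum(vapply(sets, function(s) id %in% s, logical(1)))
  }, integer(1))
  unname(profiles$patient_id[hits >= k])
}

table1_fixture <- function(seed = 1) {
  materialize_fixture(reconstruct_joint(read_marginal_table()), seed = seed)
}

# The published validation table, as printed (counts and one-decimal
# percentages), in canonical row order.
printed_table1 <- function() {
  tibble::tribble(
    ~label,                        ~n_selected, ~pct_selected, ~n_confirmed, ~ppv, ~n_not_confirmed,
    "Without using an algorithm",  219L,        100.0,         155L,         70.8, 64L,
    "Criterion 1",                 47L,         21.5,          43L,          91.5, 4L,
    "Criterion 2",                 49L,         22.4,          44L,          89.8, 5L,
    "Criterion 3",                 105L,        47.9,          80L,          76.2, 25L,
    "Criterion 1 or 2",            73L,         33.3,          64L,          87.7, 9L,
    "Criterion 1 or 3",            127L,        58.0,          101L,         79.5, 26L,
    "Criterion 2 or 3",            132L,        60.3,          102L,         77.3, 30L,
    "All 3 criteria",              9L,          4.1,           9L,           100.0, 0L,
    "2 out of 3 criteria",         52L,         23.7,          49L,          94.2, 3L,
    "1 out of 3 criteria",         140L,        63.9,          109L,         77.9, 31L
  )
}
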