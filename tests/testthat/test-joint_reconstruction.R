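joint_cell <- function(j, conf, p1, p2, p3) {
  j$n[j$confirmed == conf & j$c1 == p1 & j$c2 == p2 & j$c3 == p3]
}

test_that("pairwise intersections follow the printed unions by inclusion-exclusion", {
  m <- read_marginal_table()
  j <- reconstruct_joint(m)
  # oracle: n(C1 & C2) = n(C1) + n(C2) - n(C1 | C2), computed directly
  # from the printed counts, must equal the reconstructed 11x + 111 cells
  for (cls in c("confirmed", "not_confirmed")) {
    conf <- cls == "confirmed"
    expected_12 <- m[[cls]]$c1 + m[[cls]]$c2 - m[[cls]]$c1_or_c2
    got_12 <- joint_cell(j, conf, TRUE, TRUE, FALSE) +
      joint_cell(j, conf, TRUE, TRUE, TRUE)
    expect_identical(got_12, as.integer(expected_12))
  }
  # frozen values of that oracle: 43 + 44 - 64 = 23 and 4 + 5 - 9 = 0
  expect_identical(joint_cell(j, TRUE, TRUE, TRUE, FALSE) +
                     joint_cell(j, TRUE, TRUE, TRUE, TRUE), 23L)
  expect_identical(joint_cell(j, FALSE, TRUE, TRUE, FALSE) +
                     joint_cell(j, FALSE, TRUE, TRUE, TRUE), 0L)
})

test_that("disjoint toy marginals give an empty overlap pattern", {
  m <- marginal_table(
    confirmed = list(total = 2, c1 = 1, c2 = 1, c3 = 0, c1_or_c2 = 2,
                     c1_or_c3 = 1, c2_or_c3 = 1, all_three = 0,
                     at_least_two = 0, at_least_one = 2),
    not_confirmed = list(total = 0, c1 = 0, c2 = 0, c3 = 0, c1_or_c2 = 0,
                         c1_or_c3 = 0, c2_or_c3 = 0, all_three = 0,
                         at_least_two = 0, at_least_one = 0)
  )
  j <- reconstruct_joint(m)
  expect_identical(joint_cell(j, TRUE, TRUE, TRUE, FALSE), 0L)
  expect_identical(joint_cell(j, TRUE, TRUE, FALSE, FALSE), 1L)
  expect_identical(joint_cell(j, TRUE, FALSE, TRUE, FALSE), 1L)
})

test_that("the held-out k-of-3 rows are recovered with zero residual", {
  m <- read_marginal_table()
  res <- verify_consistency(reconstruct_joint(m), m)
  held_out <- res[res$quantity %in% c("at_least_one", "at_least_two"), ]
  expect_identical(nrow(held_out), 4L)
  expect_true(all(held_out$residual == 0))
  expect_identical(
    held_out$recomputed[held_out$class == "confirmed" &
                          held_out$quantity == "at_least_two"], 49L)
  expect_identical(
    held_out$recomputed[held_out$class == "not_confirmed" &
                          held_out$quantity == "at_least_one"], 31L)
  expect_true(all(res$residual == 0))
})

test_that("reconstruction inverts forward marginalization on random joints", {
  for (seed in 1:40) {
    j <- random_joint(seed)
    back <- reconstruct_joint(compute_marginals(j))
    expect_equal(as.data.frame(back), as.data.frame(j))
  }
})

test_that("inconsistent marginals raise an error naming the negative pattern", {
  # singles overlap-free by the unions, but their sum exceeds the total
  expect_error(
    reconstruct_joint(marginal_table(
      confirmed = list(total = 8, c1 = 5, c2 = 5, c3 = 0, c1_or_c2 = 10,
                       c1_or_c3 = 5, c2_or_c3 = 5, all_three = 0,
                       at_least_two = 0, at_least_one = 10),
      not_confirmed = list(total = 0, c1 = 0, c2 = 0, c3 = 0, c1_or_c2 = 0,
                           c1_or_c3 = 0, c2_or_c3 = 0, all_three = 0,
                           at_least_two = 0, at_least_one = 0)
    )),
    "000", class = "ia_inconsistency_error"
  )
  # a pairwise intersection below the triple intersection
  expect_error(
    reconstruct_joint(marginal_table(
      confirmed = list(total = 20, c1 = 5, c2 = 5, c3 = 5, c1_or_c2 = 10,
                       c1_or_c3 = 8, c2_or_c3 = 8, all_three = 2,
                       at_least_two = 2, at_least_one = 10),
      not_confirmed = list(total = 0, c1 = 0, c2 = 0, c3 = 0, c1_or_c2 = 0,
                           c1_or_c3 = 0, c2_or_c3 = 0, all_three = 0,
                           at_least_two = 0, at_least_one = 0)
    )),
    class = "ia_inconsistency_error"
  )
})

test_that("materialized fixtures realize their joint exactly", {
  j <- random_joint(99, max_count = 6)
  fix <- materialize_fixture(j, seed = 5)
  expect_identical(n_patients(fix), sum(j$n))
  prof <- extract_profiles(select_cohort(fix))
  realized <- dplyr::count(prof, confirmed, c1, c2, c3, name = "n")
  expected <- as_tibble(j)[j$n > 0, ]
  merged <- dplyr::left_join(expected, realized,
                             by = c("confirmed", "c1", "c2", "c3"),
                             suffix = c("_joint", "_realized"))
  expect_identical(merged$n_realized, merged$n_joint)
})

test_that("an all-zero joint materializes to an empty cohort", {
  pat <- criterion_patterns()
  j <- iavalidate:::new_joint(tibble::tibble(
    confirmed = rep(c(TRUE, FALSE), each = 8),
    dplyr::bind_rows(pat, pat), n = 0L))
  expect_identical(n_patients(materialize_fixture(j, seed = 1)), 0L)
})
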