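# Reconstructing the 8-pattern x 2-class joint distribution of criterion
# outcomes from a published marginal count table, via inclusion-exclusion
# and Moebius inversion. The marginal system is overdetermined (10 printed
# counts per class, 8 unknowns): the reconstruction uses only the totals,
# the three single-criterion counts, the three pairwise-union counts and
# the triple intersection; the at-least-1 and at-least-2 rows are reserved
# as held-out consistency checks.

marginal_fields <- c("total", "c1", "c2", "c3", "c1_or_c2", "c1_or_c3",
                     "c2_or_c3", "all_three", "at_least_two", "at_least_one")

#' Build a marginal count table
#'
#' Per confirmation class (confirmed / not confirmed), the ten published
#' counts: class total, the three single-criterion counts, the three
#' pairwise-union counts, the triple intersection, and the at-least-2 and
#' at-least-1 combinator counts.
#'
#' @param confirmed,not_confirmed named lists (or vectors) with entries
#'   `total`, `c1`, `c2`, `c3`, `c1_or_c2`, `c1_or_c3`, `c2_or_c3`,
#'   `all_three`, `at_least_two`, `at_least_one`.
#' @return an `ia_marginal_table`.
#' @export
marginal_table <- function(confirmed, not_confirmed) {
  check_class <- function(m, name) {
    m <- as.list(m)
    missing <- setdiff(marginal_fields, names(m))
    if (length(missing) > 0) {
      ia_abort(sprintf("%s class: missing count(s): %s", name,
                       paste(missing, collapse = ", ")),
               "ia_schema_error")
    }
    m <- lapply(m[marginal_fields], as.integer)
    v <- unlist(m)
    if (any(is.na(v)) || any(v < 0)) {
      ia_abort(sprintf("%s class: counts must be non-negative integers",
                       name), "ia_inconsistency_error")
    }
    if (any(v[c("c1", "c2", "c3")] > v["total"])) {
      ia_abort(sprintf("%s class: a single-criterion count exceeds the total",
                       name), "ia_inconsistency_error")
    }
    unions <- rbind(c("c1_or_c2", "c1", "c2"),
                    c("c1_or_c3", "c1", "c3"),
                    c("c2_or_c3", "c2", "c3"))
    for (i in seq_len(nrow(unions))) {
      if (v[unions[i, 1]] < max(v[unions[i, 2]], v[unions[i, 3]])) {
        ia_abort(sprintf("%s class: %s is smaller than one of its members",
                         name, unions[i, 1]), "ia_inconsistency_error")
      }
    }
    m
  }
  structure(list(confirmed = check_class(confirmed, "confirmed"),
                 not_confirmed = check_class(not_confirmed, "not_confirmed")),
            class = "ia_marginal_table")
}

#' Read a marginal table from a YAML file
#'
#' The package ships `extdata/table1_marginals.yaml`, a transcription of
#' the published validation table for the 219-patient L88 cohort; that file
#' is the default.
#'
#' @param path YAML file with top-level keys `confirmed` and
#'   `not_confirmed`, each holding the ten counts of [marginal_table()].
#' @return an `ia_marginal_table`.
#' @export
read_marginal_table <- function(path = system.file("extdata",
                                                   "table1_marginals.yaml",
                                                   package = "iavalidate")) {
  if (!file.exists(path)) {
    ia_abort(sprintf("marginal table file not found: %s", path),
             "ia_schema_error")
  }
  m <- yaml::read_yaml(path)
  if (!all(c("confirmed", "not_confirmed") %in% names(m))) {
    ia_abort("marginal table file needs 'confirmed' and 'not_confirmed' keys",
             "ia_schema_error")
  }
  marginal_table(m$confirmed, m$not_confirmed)
}

#' The eight criterion patterns
#'
#' @return tibble with logical columns `c1`, `c2`, `c3`, eight rows in
#'   binary order `000`, `001`, ..., `111` (criterion 1 as the most
#'   significant bit).
#' @export
criterion_patterns <- function() {
  g <- expand.grid(c3 = c(FALSE, TRUE), c2 = c(FALSE, TRUE),
                   c1 = c(FALSE, TRUE), KEEP.OUT.ATTRS = FALSE)
  as_tibble(g[, c("c1", "c2", "c3")])
}

pattern_label <- function(c1, c2, c3) {
  paste0(as.integer(c1), as.integer(c2), as.integer(c3))
}

new_joint <- function(df) {
  df <- as_tibble(df)
  stopifnot(all(c("confirmed", "c1", "c2", "c3", "n") %in% names(df)))
  if (any(df$n < 0)) {
    ia_abort("joint counts must be non-negative", "ia_inconsistency_error")
  }
  df$n <- as.integer(df$n)
  structure(df, class = c("ia_joint", class(tibble())))
}

reconstruct_class <- function(m, class_name) {
  with(m, {
    pair <- c(c1_c2 = c1 + c2 - c1_or_c2,
              c1_c3 = c1 + c3 - c1_or_c3,
              c2_c3 = c2 + c3 - c2_or_c3)
    if (any(pair < all_three)) {
      ia_abort(sprintf(
        "%s class: pairwise intersection(s) below the triple intersection: %s",
        class_name, paste(names(pair)[pair < all_three], collapse = ", ")),
        "ia_inconsistency_error")
    }
    n <- c(
      "111" = all_three,
      "110" = pair[["c1_c2"]] - all_three,
      "101" = pair[["c1_c3"]] - all_three,
      "011" = pair[["c2_c3"]] - all_three,
      "100" = c1 - pair[["c1_c2"]] - pair[["c1_c3"]] + all_three,
      "010" = c2 - pair[["c1_c2"]] - pair[["c2_c3"]] + all_three,
      "001" = c3 - pair[["c1_c3"]] - pair[["c2_c3"]] + all_three
    )
    n <- c(n, "000" = total - sum(n))
    if (any(n < 0)) {
      ia_abort(sprintf(
        "%s class: negative reconstructed count for pattern(s) %s",
        class_name, paste(names(n)[n < 0], collapse = ", ")),
        "ia_inconsistency_error")
    }
    n
  })
}

#' Reconstruct the joint criterion-pattern distribution from marginals
#'
#' Per confirmation class, pairwise intersections follow from the printed
#' unions by inclusion-exclusion (`n(Ci & Cj) = n(Ci) + n(Cj) -
#' n(Ci | Cj)`); with the triple intersection given, all eight pattern
#' counts follow by Moebius inversion. Any negative intermediate or final
#' count raises an inconsistency error naming the offending pattern. The
#' at-least-1 / at-least-2 rows of the marginal table are NOT used here;
#' check them afterwards with [verify_consistency()].
#'
#' @param m an [marginal_table()].
#' @return an `ia_joint`: tibble with logical `confirmed`, `c1`, `c2`,
#'   `c3` and integer `n`, 16 rows (confirmed block first, patterns in
#'   [criterion_patterns()] order).
#' @export
reconstruct_joint <- function(m) {
  stopifnot(inherits(m, "ia_marginal_table"))
  pat <- criterion_patterns()
  one_class <- function(class_name, conf_flag) {
    counts <- reconstruct_class(m[[class_name]], class_name)
    tibble(confirmed = conf_flag, pat,
           n = as.integer(counts[pattern_label(pat$c1, pat$c2, pat$c3)]))
  }
  new_joint(dplyr::bind_rows(one_class("confirmed", TRUE),
                             one_class("not_confirmed", FALSE)))
}

#' Forward map: marginal counts of a joint distribution
#'
#' The trivial direction: sums the 16 pattern cells into the ten published
#' counts per class. `reconstruct_joint(compute_marginals(j))` is the
#' identity for every non-negative joint.
#'
#' @param joint an `ia_joint`.
#' @return an `ia_marginal_table`.
#' @export
compute_marginals <- function(joint) {
  stopifnot(inherits(joint, "ia_joint"))
  one_class <- function(conf_flag) {
    j <- joint[joint$confirmed == conf_flag, ]
    k <- j$c1 + j$c2 + j$c3
    list(total = sum(j$n),
         c1 = sum(j$n[j$c1]), c2 = sum(j$n[j$c2]), c3 = sum(j$n[j$c3]),
         c1_or_c2 = sum(j$n[j$c1 | j$c2]),
         c1_or_c3 = sum(j$n[j$c1 | j$c3]),
         c2_or_c3 = sum(j$n[j$c2 | j$c3]),
         all_three = sum(j$n[k == 3]),
         at_least_two = sum(j$n[k >= 2]),
         at_least_one = sum(j$n[k >= 1]))
  }
  marginal_table(one_class(TRUE), one_class(FALSE))
}

#' Residuals between a joint distribution and a printed marginal table
#'
#' Recomputes every marginal count from the joint and subtracts the printed
#' value. Because the printed system is overdetermined, the at-least-1 and
#' at-least-2 rows act as held-out checks of the reconstruction: a joint
#' reconstructed from an internally consistent table has all residuals
#' exactly zero.
#'
#' @param joint an `ia_joint`.
#' @param m an [marginal_table()].
#' @return tibble with `class`, `quantity`, `printed`, `recomputed`,
#'   `residual` (recomputed minus printed), 20 rows.
#' @export
verify_consistency <- function(joint, m) {
  stopifnot(inherits(joint, "ia_joint"), inherits(m, "ia_marginal_table"))
  rec <- compute_marginals(joint)
  one_class <- function(class_name) {
    tibble(class = class_name, quantity = marginal_fields,
           printed = unname(unlist(m[[class_name]][marginal_fields])),
           recomputed = unname(unlist(rec[[class_name]][marginal_fields])))
  }
  out <- dplyr::bind_rows(one_class("confirmed"), one_class("not_confirmed"))
  out$residual <- out$recomputed - out$printed
  out
}
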