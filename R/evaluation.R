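# Validation metrics: PPV (fraction confirmed among selected) and coverage
# (fraction of the coded cohort retained). The report mirrors the standard
# layout of code-validation studies: a baseline row for the bare code,
# then one row per candidate algorithm.

#' Positive predictive value of a selection
#'
#' @param selected character vector of selected `patient_id`s (must be a
#'   subset of the profile ids).
#' @param profiles a profile tibble (see [extract_profiles()]).
#' @return fraction of selected patients whose diagnosis is confirmed, in
#'   `[0, 1]`; `NA_real_` for an empty selection (0/0 is undefined and
#'   reporting 0 would corrupt PPV/coverage trade-off curves).
#' @export
ppv <- function(selected, profiles) {
  if (!all(selected %in% profiles$patient_id)) {
    ia_abort("selected ids not present in profiles", "ia_domain_error")
  }
  if (length(selected) == 0) {
    return(NA_real_)
  }
  mean(profiles$confirmed[profiles$patient_id %in% selected])
}

#' Coverage and exclusion of a selection
#'
#' @param selected character vector of selected `patient_id`s.
#' @param n_total cohort size (> 0).
#' @return list with `coverage` (|selected| / n_total) and `exclusion`
#'   (its complement).
#' @export
coverage <- function(selected, n_total) {
  stopifnot(n_total > 0)
  cov <- length(selected) / n_total
  list(coverage = cov, exclusion = 1 - cov)
}

validation_row <- function(label, selected, profiles, n_total) {
  n_sel <- length(selected)
  n_conf <- if (n_sel == 0) 0L else
    sum(profiles$confirmed[profiles$patient_id %in% selected])
  tibble(
    label = label,
    n_selected = as.integer(n_sel),
    pct_selected = round_half_up(100 * n_sel / n_total, 1),
    n_confirmed = as.integer(n_conf),
    ppv = if (n_sel == 0) NA_real_ else
      round_half_up(100 * n_conf / n_sel, 1),
    n_not_confirmed = as.integer(n_sel - n_conf)
  )
}

#' Evaluate a set of selection rules
#'
#' @param profiles a profile tibble (see [extract_profiles()]).
#' @param specs named list of [algorithm_spec()] objects; names become row
#'   labels.
#' @return an `ia_validation_report`: a tibble with columns `label`,
#'   `n_selected`, `pct_selected`, `n_confirmed`, `ppv` (percentage
#'   confirmed among selected, one-decimal, `NA` when nobody is selected)
#'   and `n_not_confirmed`, with the no-algorithm baseline as first row and
#'   the cohort size in attribute `n_total`. Percentages are rounded half
#'   away from zero to one decimal; the underlying counts are exact.
#' @export
validation_report <- function(profiles, specs) {
  if (nrow(profiles) == 0) {
    ia_abort("cannot evaluate an empty cohort", "ia_domain_error")
  }
  n_total <- nrow(profiles)
  rows <- dplyr::bind_rows(
    validation_row("Without using an algorithm", profiles$patient_id,
                   profiles, n_total),
    dplyr::bind_rows(lapply(names(specs), function(lbl) {
      validation_row(lbl, apply_algorithm(profiles, specs[[lbl]]),
                     profiles, n_total)
    }))
  )
  structure(rows, n_total = n_total,
            class = c("ia_validation_report", class(rows)))
}

#' The canonical nine-algorithm validation report
#'
#' Evaluates the three single criteria, the three pairwise unions, and the
#' three k-of-3 combinators (all three, at least two, at least one) in the
#' conventional order, preceded by the no-algorithm baseline.
#'
#' @inheritParams validation_report
#' @return an `ia_validation_report` with ten rows.
#' @export
table1_report <- function(profiles) {
  validation_report(profiles, canonical_specs())
}

canonical_specs <- function() {
  list(
    "Criterion 1" = algorithm_spec(1),
    "Criterion 2" = algorithm_spec(2),
    "Criterion 3" = algorithm_spec(3),
    "Criterion 1 or 2" = algorithm_spec(c(1, 2), 1),
    "Criterion 1 or 3" = algorithm_spec(c(1, 3), 1),
    "Criterion 2 or 3" = algorithm_spec(c(2, 3), 1),
    "All 3 criteria" = algorithm_spec(1:3, 3),
    "2 out of 3 criteria" = algorithm_spec(1:3, 2),
    "1 out of 3 criteria" = algorithm_spec(1:3, 1)
  )
}

#' @export
print.ia_validation_report <- function(x, ...) {
  cat(sprintf("Validation report (n = %d)\n", attr(x, "n_total")))
  df <- as.data.frame(x)
  df$selected <- sprintf("%d (%.1f%%)", df$n_selected, df$pct_selected)
  df$confirmed <- ifelse(is.na(df$ppv), sprintf("%d (--)", df$n_confirmed),
                         sprintf("%d (%.1f%%)", df$n_confirmed, df$ppv))
  print(df[, c("label", "selected", "confirmed", "n_not_confirmed")],
        row.names = FALSE, right = FALSE)
  invisible(x)
}
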