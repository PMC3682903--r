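# Reference standard: a coded IA diagnosis counts as confirmed when the
# chart review found at least one confirmatory specialist diagnosis term.
# The confirmed flag is always recomputed from the stored term set, never
# read from a file, so the reference standard stays auditable.

normalize_term <- function(x) {
  gsub("\\s+", " ", tolower(trimws(x)))
}

#' Confirmatory diagnosis vocabulary
#'
#' The controlled vocabulary of specialist diagnosis terms that confirm an
#' inflammatory-arthritis code. Terms are matched exactly after
#' normalization (lower case, collapsed whitespace); synonyms such as "RA"
#' must be mapped into the vocabulary explicitly rather than relying on
#' substring matching, which would misfire on phrases like
#' "polyarthritis ruled out".
#'
#' @param terms character vector of confirmatory terms.
#' @return an `ia_vocabulary` object.
#' @export
confirmation_vocabulary <- function(terms = c("oligoarthritis",
                                              "polyarthritis",
                                              "rheumatoid arthritis",
                                              "spondyloarthropathy")) {
  terms <- unique(normalize_term(terms))
  if (length(terms) == 0 || any(terms == "")) {
    ia_abort("vocabulary must contain at least one non-empty term",
             "ia_config_error")
  }
  structure(list(confirmatory_terms = terms), class = "ia_vocabulary")
}

#' Confirm an inflammatory-arthritis diagnosis from chart-review terms
#'
#' @param terms character vector of diagnosis terms found for one patient.
#' @param vocab an [confirmation_vocabulary()] object.
#' @return `TRUE` iff any normalized term is in the vocabulary. Monotone in
#'   the term set: adding terms can never revoke a confirmation.
#' @examples
#' confirm_ia(c("gout", "rheumatoid arthritis"))  # TRUE
#' confirm_ia(c("gout", "osteoarthritis"))        # FALSE
#' @export
confirm_ia <- function(terms, vocab = confirmation_vocabulary()) {
  stopifnot(inherits(vocab, "ia_vocabulary"))
  any(normalize_term(terms) %in% vocab$confirmatory_terms)
}

#' Raw validity of the coded diagnosis
#'
#' The positive predictive value of the diagnostic code itself: the
#' fraction of cohort patients whose chart review confirms the diagnosis,
#' before any case-finding algorithm is applied. Identical to the PPV of
#' the trivial "select everyone" algorithm.
#'
#' @param x an `ia_cohort` (non-empty).
#' @param vocab an [confirmation_vocabulary()] object.
#' @return list with `n_confirmed`, `n_total` and `fraction`.
#' @export
raw_validity <- function(x, vocab = confirmation_vocabulary()) {
  stopifnot(inherits(x, "ia_cohort"))
  if (n_patients(x) == 0) {
    ia_abort("raw_validity is undefined on an empty cohort",
             "ia_domain_error")
  }
  confirmed <- vapply(x$patients$specialist_terms, confirm_ia, logical(1),
                      vocab = vocab)
  list(n_confirmed = sum(confirmed), n_total = length(confirmed),
       fraction = mean(confirmed))
}
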