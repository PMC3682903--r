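# Internal helpers shared across modules.

ia_abort <- function(message, class, ...) {
  rlang::abort(message, class = c(class, "ia_error"), ...)
}

#' Round half away from zero
#'
#' Rounds to `digits` decimals with halves moving away from zero, the
#' convention used when reporting percentages (e.g. 155/219 -> 70.8). Base
#' `round()` rounds half to even, which disagrees on exact halves.
#'
#' @param x numeric vector.
#' @param digits number of decimal places (default 1).
#' @return numeric vector of the same length.
#' @examples
#' round_half_up(70.75, 1)  # 70.8
#' round_half_up(-2.5, 0)   # -3
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# ICPC rubric matching: case-insensitive, whitespace-trimmed; a sub-rubric
# such as "L88.01" matches the root rubric "L88" by its prefix before the dot.
icpc_matches <- function(codes, rubric) {
  norm <- toupper(trimws(codes))
  rub <- toupper(trimws(rubric))
  root <- sub("\\..*$", "", norm)
  !is.na(codes) & (norm == rub | root == rub)
}

# ATC membership by hierarchical prefix (e.g. "L04A" covers "L04AX03").
atc_in_catalog <- function(atc_codes, catalog) {
  norm <- toupper(trimws(atc_codes))
  hit <- rep(FALSE, length(norm))
  for (p in catalog$dmard_biologic_atc_prefixes) {
    hit <- hit | startsWith(norm, toupper(trimws(p)))
  }
  hit & !is.na(atc_codes)
}

# Shift a Date by whole years; Feb 29 maps to Feb 28 in non-leap years.
shift_years <- function(date, years) {
  lt <- as.POSIXlt(date)
  lt$year <- lt$year + years
  out <- as.Date(lt)
  rolled <- !is.na(out) & format(date, "%m-%d") == "02-29" &
    format(out, "%m-%d") == "03-01"
  out[rolled] <- out[rolled] - 1L
  out
}

# Largest-remainder apportionment of n units over non-negative weights.
# Ties on the fractional part are broken by position (first weight wins),
# which keeps the result deterministic.
largest_remainder <- function(weights, n) {
  if (any(weights < 0)) {
    ia_abort("apportionment weights must be non-negative", "ia_config_error")
  }
  expected <- weights / sum(weights) * n
  base <- floor(expected)
  short <- n - sum(base)
  if (short > 0) {
    ord <- order(expected - base, decreasing = TRUE)
    base[ord[seq_len(short)]] <- base[ord[seq_len(short)]] + 1
  }
  as.integer(base)
}
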