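---
title: "Validating coded inflammatory arthritis diagnoses in primary-care EMRs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating coded inflammatory arthritis diagnoses in primary-care EMRs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iavalidate)
```

## The problem

In gatekeeper health systems, general-practice electronic medical records
(EMRs) are near-complete morbidity registers: every inhabitant is listed
with a practice and specialist care is reached through the GP. Diagnoses
are recorded with ICPC-1 codes, and rubric L88 codes inflammatory
arthritis (IA) — rheumatoid arthritis, psoriatic arthritis, ankylosing
spondylitis and related chronic rheumatic diseases. IA is hard to
distinguish from osteoarthritis or gout at onset, so an L88 code is not
always a true IA diagnosis: a code may record an initial suspicion that a
specialist later revises.

`iavalidate` implements the standard validation design for this setting:

1. select every patient ever registered with the index code, aged at
   least 30 at the first coded event (excluding juvenile arthritis);
2. compare the code against a chart-review reference standard — the
   diagnosis is *confirmed* when specialist correspondence contains a
   confirmatory diagnosis term;
3. evaluate rule-based case-finding algorithms that trade coverage
   (fraction of coded patients retained) against positive predictive
   value (PPV, fraction of retained patients confirmed).

Sensitivity is out of scope by design: the chart review only examines
patients who *carry* the code, so false negatives are unobservable in
this design and no sensitivity, specificity or NPV is reported.

## Data model

A cohort is four linked tables keyed by `patient_id`:

* **patients** — sex, birth date, and the set of specialist diagnosis
  terms found at chart review;
* **contacts** — dated GP consultations with an ICPC-1 code;
* **episodes** — disease episodes (the period between the first and last
  contact for one health problem), with an ICPC-1 code;
* **prescriptions** — dated prescriptions with an ATC code, an optional
  linked ICPC code (the coded indication), and a repeat flag. A *repeat
  prescription* is one issued without a consultation — the GP continuing
  a therapy a specialist initiated.

The confirmed flag is never stored: it is always recomputed from the term
set via `confirm_ia()`, so the reference standard stays auditable. Term
matching is exact on normalized strings (lower case, collapsed
whitespace), not substring matching; "polyarthritis ruled out" must not
confirm, and synonyms like "RA" are handled by extending the vocabulary,
not by fuzzy matching. We treat any occurrence of a confirmatory term as
confirming; the data model carries no dates on terms, so "diagnosis
changed later" logic is not expressible and is a known limitation.

## The three criteria and their combinators

`extract_profiles()` reduces each patient to a feature row and three
booleans:

* **Criterion 1** — a repeat prescription for a DMARD or biological
  agent. The medication catalog is a set of ATC prefixes (default: L04A,
  L01BA01, P01BA02, A07EC01, M01CB, M01CC01 — the standard DMARD mapping
  in pharmacoepidemiology; configurable because the class boundary is a
  modelling choice). No ICPC link is required on the prescription:
  specialists initiate DMARDs without a GP-coded indication.
* **Criterion 2** — at least four index-coded contacts *or* one
  index-coded episode, combined with at least two prescriptions linked to
  the index code, DMARDs/biologicals excluded from that count. Distinct
  prescription records count, with no per-drug or per-date deduplication,
  and same-day contacts count separately: the source database records
  contact events, and no deduplication rule is part of the design.
* **Criterion 3** — age at the first index-coded event between 30 and 61
  years inclusive. The 61-year cut-off is the cohort mean age at
  diagnosis; patients first coded above it are more likely to have
  osteoarthritis or another mimic. Both bounds are parameters
  (`min_age`, `age_cutoff`).

`algorithm_spec(criteria, min_satisfied)` expresses every rule studied:
single criteria, pairwise unions (`k = 1` over two criteria), and the
k-of-3 combinators. Selections nest in `k`, and `k = 1` / `k = n` reduce
to set union / intersection — properties the test suite checks against a
brute-force set oracle on random cohorts.

PPV of an empty selection is reported as `NA`, not 0: 0/0 is undefined,
and printing 0 would corrupt PPV–coverage trade-off curves. Report
percentages are rounded half away from zero to one decimal (the
convention that prints 155/219 as 70.8%); counts are exact and the
underlying fractions can always be recomputed from them.

## Reconstructing the joint from a printed marginal table

Published validation tables print, per confirmation class, the class
total, the three single-criterion counts, the three pairwise-union
counts, the triple intersection, and the at-least-1 / at-least-2
combinator counts — ten numbers constraining eight unknown pattern
counts. `reconstruct_joint()` uses only totals, singles, unions and the
triple: pairwise intersections follow by inclusion–exclusion,

$$ n(C_i \cap C_j) = n(C_i) + n(C_j) - n(C_i \cup C_j), $$

and the eight pattern counts then follow by Möbius inversion. Any
negative intermediate or final count is an inconsistency error naming the
offending pattern — the package deliberately refuses to least-squares
"repair" an inconsistent table, because a published table either is or is
not internally consistent, and that is itself a finding.

The two k-of-3 rows are *held out* from the reconstruction and checked
afterwards by `verify_consistency()`: a zero residual on them is
non-trivial evidence that the printed table is internally consistent.
For the shipped table (`inst/extdata/table1_marginals.yaml`, a
transcription of the published 219-patient L88 cohort) all twenty
residuals are exactly zero, and `materialize_fixture()` then emits one
patient record per unit count whose events are constructed so profile
extraction reproduces the joint bit-exactly. The whole
reconstruct–materialize–evaluate cycle runs in well under a second.

## The synthetic cohort generator

`generate_cohort()` draws (confirmation class, criterion pattern) per
patient from a configurable joint — by default the reconstructed
published joint — and builds event records with the same construction as
the fixture. Two modes:

* **exact** — the 16 cell counts are the largest-remainder apportionment
  of `n_patients` over the cell probabilities (ties broken by cell
  position, so the result is deterministic), and the sex split is
  apportioned exactly. At the default 219 every expectation is an
  integer, so the generated cohort reproduces the published joint — and
  therefore the full validation table — exactly.
* **stochastic** — classes, patterns and sexes drawn i.i.d., for
  calibration studies at larger n.

One private random stream per cohort, seeded explicitly through the
config; identical configs give byte-identical serialized cohorts.

### Age model

The reference cohort description gives marginal moments (mean 58, SD 15
at first coded contact) *and* a hard band structure: criterion-3-positive
patients lie in [30, 61], the rest at 62 or older, with about 48% of
patients in the band. A single normal clamped to the band cannot satisfy
both: clamping N(58, 15) compresses the spread so strongly that the
marginal SD falls near 10.5 and the mean drifts above 60. The generator
therefore draws band-conditional normals whose parameters were calibrated
once, analytically against the band mix, so the *mixture* reproduces the
target moments: inside-band ages ~ N(age_mean − 13, 11·age_sd/15) clamped
to the band, outside-band ages ~ N(age_mean + 10, 10·age_sd/15) clamped
to ≥ 62. At the default mix this yields a marginal mean of ≈ 57.9 years
and SD ≈ 15.0. Changing `age_mean`/`age_sd` shifts and scales both bands
coherently, though the calibration is exact only near the default
criterion-3 mix. Birth dates are placed 30 days before the index-date
anniversary so the completed-years age at the index date is exactly the
drawn age.

### What the generator does and does not emulate

It emulates the criterion-pattern × confirmation joint, the female
fraction, the age structure, and miscoding (unconfirmed patients arise
naturally as the not-confirmed class — an L88 code with non-IA specialist
terms). It does **not** emulate practice-level clustering, longitudinal
disease progression, comorbidity, free-text notes, or realistic
prescription variety: event histories are minimal certificates of the
drawn pattern (e.g. exactly four contacts when criterion 2 holds). A
passing calibration test therefore shows the pipeline is correct on data
with the study's statistical structure; it says nothing about robustness
to the messiness of real EMR extracts beyond what the parsers validate.

## Numerical and degenerate-input choices

* Ages are completed years (floor), incrementing on the birthday; Feb 29
  births complete their year on Mar 1 in non-leap years.
* ICPC matching is case-insensitive and whitespace-trimmed; sub-rubrics
  ("L88.01") match their root rubric by the prefix before the dot.
* "Ever registered with the index code" is satisfied by a coded contact
  *or* a coded episode — both recording routes count, since either can
  carry the diagnosis; an episode needs no accompanying contact.
* Empty cohorts: `raw_validity()` and report generation refuse them
  (domain error) rather than returning NaN.
* The observation window for generated index dates (default 2003-01-01
  to 2008-12-31, inside a 2001–2010 registration period) is a parameter,
  not a constant.

## Problem sizes and test design

The test suite reproduces the published table from the 219-patient
reconstruction (sub-second), runs property checks over dozens of random
joints and random cohorts of 100–300 patients, and calibrates the
stochastic generator at n = 10 000 with fixed seeds: each of the 16
joint-cell frequencies must fall within 4 binomial standard errors of
its configured probability, and the confirmed-class frequency within 3.
Demographic calibration is deliberately loose: the reference description
(64% female, mean 58, SD 15) was itself estimated on 219 patients, so
age moments are compared at ±3 standard errors on that scale (±3.0 years
on the mean, ±2.2 on the SD), while the female fraction uses the
generated-cohort scale.

## Limitations

* The reference standard is specialist correspondence as abstracted into
  term sets; parsing real letters (negation, dates, competing diagnoses)
  is out of scope.
* False negatives are structurally invisible to this design.
* The shipped marginal table describes five practices from one national
  network; reconstruction generalizes to any table with the same ten
  counts per class, but conclusions about criterion performance do not
  automatically transfer to other coding cultures.
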