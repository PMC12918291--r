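---
title: "Privacy-preserving data quality assessment: models and design choices"
author: "dpquality"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Privacy-preserving data quality assessment: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dpquality)
```

## The problem

Federated health data networks — biobank locators, distributed research
infrastructures — need to advertise the quality of the datasets held at each
node without the nodes exposing patient-level data. Even aggregated quality
metrics can disclose: a count of one patient with a gender-incompatible
diagnosis is close to an identification. `dpquality` computes patient-level
quality checks locally and discloses only values perturbed by the Laplace
mechanism, under an explicitly accounted per-report privacy budget.

## The mechanism

A counting query $f(D)$ is released as
$$f'(D) = f(D) + \mathrm{Lap}(\Delta f / \varepsilon),$$
where $\Delta f$ is the query sensitivity — 1 for patient-level counts, and
for sample-level queries the largest number of specimens any one patient
contributes (`sample_sensitivity()`). This satisfies pure
$\varepsilon$-differential privacy ($\delta = 0$ throughout; `dp_params()`
rejects anything else).

Percentages are released as
$$\widetilde{q} = \frac{\tilde c}{\tilde n} \cdot 100,
  \qquad \tilde c = c + \eta_1,\ \tilde n = n + \eta_2,$$
with independent Laplace draws $\eta_1, \eta_2$. By default the check's
budget $\varepsilon$ is halved between numerator and denominator (each draw
at scale $\Delta f/(\varepsilon/2)$): this keeps each check's accounting
self-contained and conservative. `noisy_percentage(pair_split = FALSE)`
instead spends the full $\varepsilon$ on the numerator only — the
single-query setting that the closed-form forecasts below describe. The
denominator is clamped to $\ge 1$ and the numerator to $[0, \tilde n]$, so
disclosed percentages always lie in $[0, 100]$. Clamping, rounding (two
decimals, applied only at the reporting boundary) and low-count suppression
are all post-processing of the noised value and therefore do not weaken the
guarantee.

Running $k$ mechanisms sequentially on the same data costs
$\sum_i \varepsilon_i$ (sequential composition). The `budget_ledger` enforces
this: every check is charged *before* it runs, a charge that would exceed the
cap is refused atomically, and a refused check does not run at all
(fail-closed — unpaid results are never disclosed). Correlation-exploiting
composition is deliberately out of scope; the conservative sequential sum is
always used.

Stratification multiplies queries: a check split over $k$ strata under a
fixed total budget gives each stratum $\varepsilon_i = \varepsilon_{\rm
total}/k$, hence per-stratum noise scale $\Delta f\, k/\varepsilon_{\rm
total}$ and variance $2(\Delta f\, k/\varepsilon_{\rm total})^2$ — quadratic
in $k$. `stratification_variance()` exposes the law; the test suite verifies
the implementation reproduces it empirically.

## The check catalogue

Nine built-in checks cover the six objectively assessable quality dimensions
(accuracy, completeness, consistency, timeliness, validity, uniqueness).
They are counting predicates over a minimal FHIR R4 subset (Patient,
Condition, Specimen); no query language is parsed — the original
CQL-expressed checks are implemented as native predicates, and custom
predicates register through `register_check()`.

Several semantics were genuinely open and were fixed as follows:

* **Missing vs unsupported gender.** An absent or empty gender element
  counts toward `completeness-1`; a present non-empty token outside the
  FHIR AdministrativeGender set \{male, female, other, unknown\} counts
  toward `consistency-1`. The two numerators are disjoint.
* **Duplicates.** `uniqueness-1` counts surplus records: total records minus
  distinct ids, over total records. This is order-free and unambiguous under
  any permutation of the file.
* **Validity denominator.** `validity-1` ("patients having conditions with
  invalid ICD-10 codes") is computed over patients with at least one linked
  condition. Over all patients the check would be structurally capped at
  100% minus the no-condition rate, making a high invalidity rate and a
  20% no-condition rate mutually incoherent; over condition-bearing patients
  both rates coexist and the generator's parameter-recovery property is
  exact. A patient fails if *any* of their codes is invalid; a missing code
  is invalid.
* **Structural ICD-10 validity** uses the pattern
  `^[A-TV-Z][0-9][0-9A-B](\.[0-9A-TV-Z]{1,4})?$`; supplying a code list
  switches to terminology membership. Synthetic invalid codes are built to
  fail the pattern and to avoid the gender-specific C5x/C6x roots so they
  can never leak into the incompatibility numerator.
* **Incompatibility table.** C60–C63 are treated as male-only and C51–C58 as
  female-only by default; the table is a plain tibble and fully
  configurable. Patients with missing or unsupported gender cannot be
  scored and are not counted.
* **Timeliness.** Records older than 365 days (configurable) *or with no
  provenance at all* count as stale — absent `meta.lastUpdated` is the worse
  case.
* **Survival.** `accuracy-3` reports the percent of stratum patients whose
  deceased flag is not true (absent or false), stratified by gender
  \{female, male\}; a `deceasedDateTime` maps to deceased. This is the only
  reading of "survival rate" consistent with a boolean/absent deceased
  element.
* **Reference date.** All "now"-relative checks take an explicit reference
  date, never the wall clock, so a report is a pure function of its inputs.

Legacy spellings of two check ids (`completness-1`, `completness-2`,
`uniqness-1`) are kept as aliases so historical reports remain matchable.

## The synthetic cohort generator

`generate_cohort()` emulates a FHIR test-data generator that purposefully
injects quality errors: per patient and error class an independent Bernoulli
draw at the profile rate, in a documented fixed order (gender, deceased,
then each error class, then duplicates, then specimens), from one seeded
generator — identical specs give byte-identical serialised cohorts.

The default profile (`default_profile()`) sets each rate to the raw
prevalence observed in the reference battery over a 1,000-patient synthetic
evaluation cohort: missing gender 3.7%, unsupported gender 9.6%, no
condition 20%, invalid ICD-10 codes 96.9% (of condition-bearing patients),
duplicate ids 9.7%, birth-date anomalies 5.6%, incompatible diagnoses 0.1%,
stale updates 0%, survival 27.6% (female) / 30.9% (male). These defaults are
the study conditions of the package's own validation and are not tuned.

Materialisation rules where classes cannot coexist on one record: missing
gender takes precedence over an unsupported token; condition-level errors
(invalid code, incompatible diagnosis) materialise only for patients that
have conditions; incompatible diagnoses additionally require a supported
binary gender. `describe_cohort()` reports exactly the materialised counts,
which equal the check numerators record for record — the
generator-vs-engine cross-oracle the test suite relies on.

Duplicate injection appends $\lceil \text{rate} \cdot n \rceil$ clone
records (same id, same field values) after the base population, so
`n_patients` counts base records and the duplicated percentage is computed
over total records. Specimens are distributed multinomially over patients
with uniform weights — a stand-in, since nothing in the emulated setting
fixes that distribution — which suffices to exercise sensitivities
$\Delta f > 1$.

What the generator does *not* emulate: clinically realistic code
frequencies, longitudinal trajectories, correlated errors (a site with poor
provenance likely also has poor coding), or non-uniform specimen loads.
Passing the recovery tests therefore shows the pipeline is unbiased under
independent error injection, not that it has been validated against real
registry data.

`synthetic_reference_cohort()` is different in kind: a deterministic
stand-in with *fixed* error counts (37 missing-gender records, 96
unsupported, 200 condition-less, 97 duplicate clones among 1,000 total
records, and so on), built so the battery's raw values are exactly
reproducible. It is labelled synthetic; it is not a deposited dataset.

## Utility and risk forecasts

For a ratio $q = k/n$ with only the numerator noised at sensitivity 1,
$$\mathrm{SD}[\widetilde q] = \frac{\sqrt 2}{n \varepsilon},$$
so at $n = 10$, $\varepsilon = 1$ the SD is $\approx 0.141$ — noise of the
same order as the quantity. `release_gate()` therefore withholds releases
below a minimum cohort size, 30 by default and inclusive at the boundary,
and advises aggregating across sites or periods instead. The forecast is
validated against simulation (10⁴ noisy releases) in the test suite.

Disclosure risk is summarised by the worst-case Bayes update: an
$\varepsilon$-DP release bounds the likelihood ratio between neighbouring
datasets by $e^\varepsilon$, so a prior inclusion certainty $P_{\rm in}$
becomes at most
$$P_{\rm out} = \frac{e^\varepsilon P_{\rm in}}
  {e^\varepsilon P_{\rm in} + 1 - P_{\rm in}}.$$
This bound is not unique in the literature, but it is the standard
single-query likelihood-ratio argument and reproduces the reference point
(prior 0.1, $\varepsilon = 2$, posterior $\approx 0.45$); it is adopted for
`posterior_certainty()` and the `certainty_band()` plot (upper band
$e^{\varepsilon}$, lower band $e^{-\varepsilon}$; the bands satisfy
$\mathrm{lower}(p) = 1 - \mathrm{upper}(1-p)$). A 95%-interval statement
about small-cohort ratios sometimes quoted alongside these formulas is not
derivable from them alone and is deliberately not implemented.

```{r band, fig.width = 5, fig.height = 4, eval = requireNamespace("ggplot2", quietly = TRUE)}
plot_certainty_band(epsilons = c(0.5, 1, 2))
```

## Reports and the federation boundary

`build_report()` runs the battery under a fresh ledger: charge, run,
perturb, threshold. Statuses (`ok`/`warning`/`error` at 10%/30% by default)
are computed from the *disclosed* DP value, not the raw one, so any consumer
of the public report can recompute them; the thresholds are inclusive on the
lower side (a value exactly at the warning threshold is still `ok`). Raw
numerators, denominators, percentages and seed material exist only in the
local view; `export_public()` never serialises them, and
`read_public_report()` rejects any file that contains them — the central
aggregator (`aggregate_nodes()`, `federate()`) is thereby structurally
incapable of consuming local reports. Report timestamps are truncated to the
day to reduce linkage surface. Transport is the filesystem, one directory
per node; the architecture is agent/server, but no network protocol is
implemented.

Default allocation follows the reference configuration: 0.2 per check, 0.3
for the stratified check (charged once; the stratum split is internal to the
mechanism), cap 2.0. `allocation_plan()` supports per-check overrides with
either a uniform split of the leftover or a pinned flat default.

## Numerical choices

* Laplace draws use the inverse-CDF transform
  $x = -b\,\mathrm{sgn}(u)\ln(1 - 2|u|)$, $u \sim U(-\tfrac12, \tfrac12)$,
  on R's global RNG stream: reproducible under `set.seed()` and identical
  across platforms.
* Ledger cap comparisons use an absolute tolerance of $10^{-9}$ so that
  binary-float charge sequences (seven 0.2s plus 0.3 against cap 2.0) are
  not refused spuriously; reported totals are exact sums of the recorded
  entries.
* Stratum shares are computed so they sum to $\varepsilon_{\rm total}$
  exactly (the last share absorbs the float residue).
* Partial FHIR dates (`1975`, `1975-03`) compare by their earliest instant.
* Empty denominator populations raise an "insufficient population" error —
  deliberately distinct from a 0% result — which `run_battery()` captures
  per check without aborting the battery.
* Suppression of small counts (strictly below a threshold, default 10) is
  available but disabled by default.

## Problem sizes

The validation suite uses 1,000-patient cohorts for parameter recovery
(three binomial standard errors at the profile rates), $10^5$ draws for
sampler moments, $3 \times 10^4$ releases per side for the empirical
$\varepsilon$-DP histogram bound, and $10^4$ releases for the
forecast-vs-simulation agreement (5% relative tolerance). These sizes give
comfortable statistical margins for every asserted property while keeping
the full suite fast.

## Limitations

Sequential composition only; no Gaussian mechanism, Rényi accounting or
local-DP randomised response. Checks are patient-level predicates over a
minimal FHIR subset — no CQL, no profiles, no server round-trips. The
generator's independence assumptions are idealised. Budget tracking is per
report: repeated reports over time compose across reports, and nothing here
accounts for that longitudinal loss.
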