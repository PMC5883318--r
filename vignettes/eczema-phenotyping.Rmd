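---
title: "Identifying atopic eczema in coded primary-care records: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying atopic eczema in coded primary-care records: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eczemaid)
```

## The case-definition model

Atopic eczema (AE) in UK primary-care records is a worst case for
code-based phenotyping: it is chronic but rarely re-coded (most patients
carry a single diagnostic Read code over many years of follow-up), its
terminology is non-specific, and its mainstay treatments — emollients,
topical steroids — are prescribed for many other conditions. A definition
built on diagnosis codes alone under-ascertains; one built on treatments
alone over-ascertains.

`eczemaid` encodes the combined definition: a patient is a case when they
have

1. at least one event on a **core diagnosis** code list (five Read codes
   ship built in: M111.00 atopic dermatitis/eczema, M112.00 infantile
   eczema, M113.00 flexural eczema, M114.00 allergic/intrinsic eczema,
   M12z100 eczema NOS), and
2. at least **two distinct calendar dates** carrying any eczema-related
   treatment code (emollients, topical steroids, topical calcineurin
   inhibitors, topical anti-infectives, systemic immunomodulators,
   phototherapy — BNF-style groupings supplied as user code lists),

with treatments counted **at any time relative to the diagnosis**, since
symptomatic treatment often precedes the coded diagnosis. The two-date
requirement is the chronicity signal: two treatment *occasions* rather
than two codes, so two drugs issued on one day count once.

Nine stricter preset variants add, singly or in combination: steroid/TCI
specificity of one or two treatment dates (`steroid1`, `steroid2`), a
temporal link between therapy and diagnosis (`window`), a second
diagnosis date (`twocodes`, `twocodes_steroid1`, `twocodes_steroid2`),
an exclusion-free record (`no_exclusion`), a coded atopic comorbidity
(`atopy`) and a dermatology consult (`derm_consult`). Every variant only
adds constraints, so on any cohort its positive set is nested inside the
baseline positives — an invariant the test suite asserts on generated
cohorts.

### Rule-engine conventions

Several small choices in the rule engine were genuinely open; the package
fixes them as follows and keeps them switchable where noted.

* **Distinct dates, not distinct codes.** Both the diagnosis-count and
  treatment-count criteria count distinct calendar dates. A second core
  code on the same day as the first is not independent evidence of
  chronicity; it is usually the same consultation coded twice.
* **Temporal window**: "3 months before" is 91 days and "1 year after"
  is 365 days, endpoints inclusive. Month-based arithmetic would make the
  decision depend on which month the diagnosis fell in.
* **Exclusions are record-wide**: the `no_exclusion` variant rejects a
  patient with an exclusionary code at *any* time, because a competing
  diagnosis casts doubt on the whole coded history, not on a window.
* **Code matching** is exact string equality after whitespace trimming
  and alias canonicalisation (`M1120.0` → `M112.00`, `M11400` →
  `M114.00`, two typographical variants of the core codes seen in the
  wild). An optional prefix mode supports hierarchical Read-code lists
  but is off by default because the core definition enumerates literal
  codes.
* **Category precedence**: when one code appears on several lists,
  classification returns the first category in a fixed order — diagnosis
  tiers, then treatment classes (steroid, TCI, emollient,
  anti-infective, systemic, phototherapy), then flag categories — so a
  code shared between a treatment list and a flag list always acts as the
  treatment.
* **Age arithmetic** uses days/365.25; the child stratum is the
  half-open interval [0, 18) years at a configurable reference date
  (default 2013-01-01). Events outside the registration window are
  retained by default (`within_registration()` filters them), since
  treatment may legitimately be recorded around registration boundaries.

## Dating onset and last activity

`date_cohort()` estimates each patient's age at first/last core
diagnosis code and first/last treatment code. These are *proxies* for
onset and last disease activity; the package deliberately computes them
for every patient and leaves cohort conditioning (for example, restricting
"last activity" to patients with no symptoms in the year before their
last visit) to the caller, because such filters are study decisions, not
properties of the record. Ties on the first or last day resolve by
min/max over dates and are therefore order-free.

Agreement between a survey-derived estimate and the database proxy is
assessed with `bland_altman()`: differences are survey − database; the
mean difference gets a normal-approximation 95% CI (mean ± 1.96·SD/√n)
and limits of agreement mean ± 1.96·SD. The z rather than t quantile is
used throughout; at the cohort sizes this analysis is meant for (n ≥ 50)
the difference is under 2%.

## Validation statistics

The sampling design this package serves — survey the physicians of a
random sample of *algorithm positives* — identifies exactly one operating
characteristic, the **positive predictive value**. Sensitivity,
specificity and NPV are not computable without sampling
algorithm-negative patients, and the package does not pretend otherwise.

* `ppv()` defaults to the **Clopper–Pearson exact interval**
  (`qbeta(α/2, x, n−x+1)`, `qbeta(1−α/2, x+1, n−x)`), which inverts the
  binomial tails and never undercovers; Wilson and Wald are available
  for comparison. The tests cross-check the endpoints against a direct
  numeric inversion of `pbinom` to 10⁻⁹.
* Percentages render by **round-half-up to integer percent**
  (`percent_round()`), the convention of published validation tables.
* `compare_proportions()` uses Pearson χ² **without continuity
  correction**, switching to Fisher's exact test when any expected cell
  is ≤ 5. The conservative "≤" (rather than "<") keeps borderline
  tables such as 8/2 vs 2/8 — where every expected count is exactly 5 —
  on the exact path.
* `rank_sum()` is two-sided Wilcoxon with midranks: exact when both
  groups have ≤ 20 observations and no ties, otherwise the normal
  approximation without continuity correction; a zero rank variance
  (all observations identical) reports p = 1.
* `validate_cohort()` excludes patients with missing physician labels
  (unreturned or incomplete surveys) from **both** numerator and
  denominator, and reports per-variant PPV overall and by stratum,
  detection fraction against the confirmed reference set, and a
  child-vs-adult comparison.

## What the synthetic generator emulates — and what it does not

`generate_cohort()` exists so the pipeline can be exercised, calibrated
and closed-loop tested without access to restricted EHR data. Its
defaults are the study conditions the package is built around:

| parameter | default | rationale |
|---|---|---|
| `case_prevalence` | 0.13 | share of the source population carrying ≥ 1 core eczema code |
| `dx_count_mean`, `dx_count_sd` | 1.2, 0.5 | per-case core-code count: chronic disease, rarely re-coded |
| `rx_count_mean`, `rx_count_sd` | 16.3, 24.5 | per-case prescription count: heavily overdispersed |
| `confirm_prob_given_positive` | 0.86 | physician-confirmation probability among algorithm positives |
| `onset_lag_mean`, `onset_lag_sd` | 0.8 y, 5 y | recalled onset minus first recorded diagnosis age |
| `last_activity_lead_mean`, `last_activity_lead_sd` | −1.3 y, 4.5 y | recalled last activity minus last recorded code age |
| `treat_noncase_rate` | 0.5 | Poisson emollient scripts per non-case, giving ~42% of non-cases ≥ 1 prescription |
| `nonresponse_prob` | 0.055 | missing survey labels (≈ 11 per 200 surveyed) |
| flag rates (`exclusion/atopy/derm × case/non-case`) | 0.15/0.115, 0.41/0.24, 0.11/0.04 | carrier fractions of exclusionary, atopy and consult codes by case status |

Count distributions are moment-matched rather than taken at face value:

* **Core-code counts** use a **1-shifted negative binomial** with mean
  `dx_count_mean` and SD `dx_count_sd` (shifted Poisson when
  `sd² ≤ mean − 1`). A rounded truncated normal was considered and
  rejected: at (1.2, 0.5) its discretised mean is ≈ 1.28, so a generator
  built on it could never reproduce the configured mean. The shifted
  negative binomial has integer support ≥ 1 and reproduces both moments
  exactly.
* **Prescription counts** use a negative binomial matched to
  (16.3, 24.5²); the variance is ~37× the mean, far beyond Poisson. A
  configuration with `sd² ≤ mean` is rejected with a pointer to the
  `rx_dist = "poisson"` fallback rather than silently mis-matched.

Physician confirmation is simulated **as a label, not a mechanism**: after
events are generated, the baseline definition is evaluated and each
algorithm-positive patient is confirmed with probability
`confirm_prob_given_positive` (negatives carry their true-case flag).
The study design this mirrors measures exactly that conditional
probability, so the knob is direct: the realised PPV of a large generated
cohort is the configured probability up to binomial noise, which is what
the end-to-end closure test asserts (realised PPV in [0.84, 0.88] at
0.86 on 10,000 patients).

Recalled onset/last-activity ages are the first/last recorded-code age
plus unbounded normal noise. Leaving the noise unbounded is deliberate: a
real survey could not report a negative onset age, but truncating at zero
would shift the planted mean offset (strongly so for children near age
zero) and make the generator's own calibration unrecoverable by the
Bland–Altman analysis. The truth table is ground truth for closure
testing, not a simulated questionnaire.

What the generator does **not** emulate — and what passing tests
therefore do not show about real data: calendar structure (seasonality,
practice effects, consultation clustering), the breadth of the real code
vocabulary (non-core categories use a small synthetic vocabulary),
informative missingness of survey response, correlation between disease
severity and coding intensity, and any mechanism linking exclusionary
conditions to misdiagnosis. Event dates are uniform over the
registration window from a uniform random onset; per-patient event
counts are independent across categories given case status.

## Numerical and degenerate-input choices

* Empty event streams are negative phenotyping results, not errors;
  absent event classes yield `NA` dating ages.
* Sorting of events is stable: same-day events keep input order, and all
  decisions are invariant to input order (property-tested by shuffling).
* Duplicate codes within a loaded list collapse to the first entry with a
  warning; a blank code field is an error naming the line.
* Orphan events (unknown patient) are dropped with a counted warning;
  a registration window starting before the recorded birth date rejects
  the patient as a data error.
* Dates are ISO 8601 only; no day/month-order sniffing.

## Problem sizes

The shipped tests run the oracle-equivalence property on 1,000 random
≤ 10-event patients against a brute-force subset-enumeration oracle,
Fisher's exact against exhaustive hypergeometric enumeration on all 2×2
tables with margins ≤ 12, interval coverage on 10⁴ binomial replicates,
and the end-to-end closure on a 10,000-patient generated cohort — sizes
at which the Monte-Carlo error of each check is comfortably below the
asserted tolerance while the full suite stays fast enough to run on
every change.

## Known limitations

* The package validates *identification*, not severity: coded data were
  not informative enough for severity prediction in the motivating
  studies, and `rank_sum()` is provided for descriptive comparisons only.
* PPV is context-bound: a definition validated in one database transfers
  to another only insofar as coding practice and disease prevalence
  transfer. The synthetic generator makes this explicit — change its
  knobs and the realised PPV moves.
* Only the five core diagnosis codes ship with the package. The wider
  diagnosis tiers (32 likely / 74 possible codes) and all treatment,
  exclusion, atopy and consult lists are interfaces for user-supplied
  files, since those lists are maintained artefacts of their source
  terminology, not constants.
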