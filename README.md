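# eczemaid

Rule-based identification and validation of atopic eczema (AE) cases in
coded primary-care electronic health records.

## The problem

Atopic eczema is chronic, episodic and heterogeneously coded: in UK
primary-care databases (THIN, CPRD and their relatives) most patients with
eczema carry only a single diagnostic Read code, while treatment codes —
which general practitioners can enter independently of any diagnosis — are
far more frequent. Naive single-code definitions therefore misclassify
heavily, and reported AE prevalence varies several-fold with the coding
algorithm used. `eczemaid` implements the diagnosis-plus-treatment
approach to this problem:

> a patient is a case if they carry **at least one of five core eczema
> diagnosis codes** (M111.00, M112.00, M113.00, M114.00, M12z100) **and at
> least two eczema-related treatment codes on separate calendar dates**,
> at any time relative to the diagnosis.

together with nine published stricter variants (steroid/TCI-specific
treatments, a diagnosis–treatment temporal window, a second diagnosis
date, exclusion-free records, atopy codes, dermatology consults), and the
statistics used to validate such definitions against physician
confirmation:

* **PPV** with exact (Clopper–Pearson) binomial confidence intervals,
  `PPV = Pr(physician-confirmed | algorithm positive)`;
* **detection fraction** — the share of confirmed cases a stricter variant
  retains;
* stratified 2×2 comparisons (Pearson χ² / Fisher's exact);
* **Bland–Altman agreement** between recorded first/last code ages and
  physician-recalled onset / last-activity ages
  (mean difference `d̄`, 95% CI `d̄ ± 1.96·s/√n`, limits of agreement
  `d̄ ± 1.96·s`);
* Wilcoxon rank-sum comparisons of treatment intensity.

Because real THIN/CPRD extracts cannot be redistributed, the package ships
a seeded synthetic-cohort generator with planted ground truth (true case
status, physician confirmation, recalled onset/last-activity ages) so the
whole pipeline — code lists → phenotyping → dating → validation — is
testable end to end.

It is aimed at pharmaco-epidemiologists and EHR-phenotyping researchers
who need a transparent, declarative rule engine for case definitions and
the validation statistics to go with it.

## Worked example

```r
library(eczemaid)

lists <- synth_codelists()                      # core codes + synthetic vocabulary
g <- generate_cohort(synth_config(n_patients = 2000, seed = 42))

base <- phenotype_cohort(g$cohort, preset("baseline"), lists)
attr(base, "summary")
#>               n       positives positives_child positives_adult
#>            2000             195             100              95

ppv(163, 189)   # PPV from a validation study's counts
#> PPV 163/189 = 86% (clopper_pearson 95% CI 80-91%)

labels <- g$truth[, c("patient_id", "physician_confirmed", "stratum")]
validate_cohort(labels, list(
  baseline = base,
  twocodes = phenotype_cohort(g$cohort, preset("twocodes"), lists)))
#> <validation_report> reference 'baseline' with 156 confirmed cases; CI method clopper_pearson
#>
#>   variant n_tp n_pos ppv_pct ci_low_pct ci_high_pct ppv_child_pct ppv_adult_pct
#>  baseline  156   184      85         79          90            84            85
#>  twocodes   22    29      76         56          90            73            78
#>  detection_pct strata_p_value notice
#>            100      0.8233732
#>             14      1.0000000

tbl <- date_cohort(g$cohort, lists)
idx <- match(tbl$patient_id, g$truth$patient_id)
bland_altman(g$truth$true_onset_age[idx], tbl$first_dx_age)
#> Bland-Altman (n = 283): mean difference 0.79 (95% CI 0.18 to 1.40), limits of agreement -9.46 to 11.05
```

Reading the output: of 2,000 synthetic patients, 195 meet the baseline
definition. On this cohort 156 of 184 analysable positives carry a
confirmed label (85% PPV; the generator's confirmation probability is
0.86), and requiring a second diagnosis date raises stringency but
retains only 14% of confirmed cases — the PPV/detection trade-off the
variants exist to explore. The Bland–Altman mean difference of 0.79 years
recovers the generator's planted 0.8-year offset between recalled onset
and the first recorded diagnosis code.

Real cohorts enter through `read_cohort("patients.csv", "events.csv")` and
user-supplied code-list files (`load_codelist()`, three-column
`code,description,category` text); only the five core diagnosis codes are
built in.

A thin command-line front end with `simulate`, `phenotype`, `date-events`
and `validate` subcommands is installed at `inst/cli/eczemaid-cli.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/eczemaid-cli.R", package="eczemaid"))')" \
  simulate --n 1000 --seed 1 --out synth_out
```

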