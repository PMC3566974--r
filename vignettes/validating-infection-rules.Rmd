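---
title: "Validating serious-infection prediction rules across datasets: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating serious-infection prediction rules across datasets: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Serious infections — sepsis (including bacteremia), meningitis, pneumonia,
osteomyelitis, cellulitis and complicated urinary-tract infection — are rare
among acutely ill children in ambulatory care but devastating when missed.
Clinical prediction rules (CPRs) combine signs and symptoms into a
dichotomous triage verdict, and their intended use in low-prevalence settings
is *ruling out*: a useful rule should have sensitivity above 90% and a
negative likelihood ratio (NLR) of at most 0.2, so a negative result pushes
an already-low pre-test probability to near zero.

`cprvalid` implements a multi-dataset retrospective validation of four such
CPRs and two national guidelines — the five-stage decision tree (FSDT), a
primary-care pneumonia rule, an emergency-department meningitis rule, the
Yale Observation Scale (YOS), the NICE feverish-illness traffic-light system
and the Dutch GP (NHG) alarm symptoms — as a reusable pipeline: executable
rule classifiers with proxy-variable resolution, explicit missing-data
policies, diagnostic-accuracy statistics with confidence intervals,
prevalence-stratified rule-out assessment, the two standard sensitivity
analyses, and dumbbell reporting of pre-/post-test probabilities. Because
the original seven European datasets (11,023 children) are not publicly
deposited, the package ships a synthetic individual-patient-data generator
whose presets emulate their printed profiles, so every pipeline stage is
testable end to end.

## The validation procedure

For each (dataset, rule) pair the pipeline:

1. **Checks eligibility.** A required variable counts as *unrecorded* when
   neither it nor any proxy exists as a column. A dataset is not used for a
   rule when one-third or more of a guideline's features, one or more of the
   pneumonia/meningitis rule's items, or two or more of the YOS/FSDT items
   are unrecorded. Ties at exactly one-third are ineligible ("one-third or
   more"). Datasets used to derive a rule never validate it (the FSDT and
   the pneumonia rule were derived in the Belgian primary-care cohort).
2. **Reduces the rule to recorded items.** A tolerated unrecorded variable
   is dropped dataset-wide (a four-item FSDT where diarrhea was never
   recorded; a five-item YOS). This is distinct from record-level
   missingness and is what makes the published validations executable.
3. **Resolves proxies.** Original values always win; otherwise the first
   recorded proxy in a fixed order is used (e.g. respiratory distress or
   chest flaring for dyspnea, clinical sick impression for the clinician's
   gut feeling, meningeal irritation for nuchal rigidity and vice versa).
   Resolution is single-step and never recursive, which is why the mutual
   meningeal pair is well defined; the schema forbids self-proxying only.
4. **Applies the record-level missing-data policy.** The default is strict
   complete-case: any missing recorded item (after proxies) makes the record
   `not_evaluable` and excludes it from the 2×2 table — nothing is imputed,
   and a fired item does not rescue a record with other items missing. The
   labelled alternative `missing_as_absent` treats missing binary items as
   absent and scores missing Yale items 1 (normal). The NICE evaluation has
   its own tolerance: a record is not evaluable only when more than
   one-third of the recorded configured features are missing; missing
   features within tolerance count as absent.
5. **Computes accuracy.** Sensitivity, specificity and predictive values
   carry Clopper–Pearson exact binomial intervals; prevalence carries a Wald
   interval; likelihood ratios use the log-normal method
   `exp(ln LR ± z·sqrt(1/x1 − 1/n1 + 1/x0 − 1/n0))`. These methods were
   chosen by reverse-engineering the published values (18/20 reproduces
   "68 to 99" only under the exact interval; the prevalence bounds match the
   normal approximation; the reconstructed low-prevalence FSDT table
   reproduces "0.2 (0.1 to 0.9)" under the log method). Every estimate
   records its method.
6. **Stratifies and assesses rule-out.** The prevalence stratum — LP below
   5%, IP 5 to 20%, HP above 20% — is assigned from the prevalence of the
   *rule's target condition* among evaluable records, so a dataset can be HP
   for serious infection and LP for meningitis. Rule-out adequacy requires
   sensitivity strictly above 90% and NLR ≤ 0.2.

```{r}
library(cprvalid)
datasets <- lapply(setNames(preset_names(), preset_names()),
                   function(p) generate(preset_profile(p), seed = 42))
report <- run_validation(datasets)
report_to_table(report)
```

## Rule encodings and threshold conventions

Threshold comparisons are strict as worded in the source definitions:
temperature *greater than* 39.5 °C, Yale score *greater than* the cutoff
(8 or 10; the package exposes both and the comparison is configurable), and
the FSDT age window is the inclusive 15-to-29-months band, implemented as
`[15, 30)` on continuous months. The FSDT is a flat any-of whose sequential
order affects only which item is credited as having fired, never the
verdict. The NICE feature list (five amber, four red features over shared
schema variables) is a reconstruction of the 2007 guideline shipped as
editable configuration; positivity is any amber or red feature, and the
result also reports the highest category reached. Rules, proxy maps,
schemas and generator profiles all round-trip through YAML, so new rules
can be added without code changes.

## What the generator emulates — and what it does not

Each preset profile fixes:

* **n and case count** exactly as printed, with the case count reconstructed
  as the integer consistent with the printed prevalence and its CI
  (Van den Bruel 33/4102, Roukema 216/1750, Bleeker 137/595, Monteny 20/506,
  Brent 147/2777, Thompson 264/700, Oostenbrink 260/593). Case counts are
  fixed by design, never resampled, so empirical prevalence is exact. For
  Oostenbrink, 260 cases reproduce the printed point estimate (43.8%) but
  the Wald upper bound computes to 47.8 against a printed 47.9; no integer
  reproduces both, and the point estimate was given priority.
* **Component diagnoses.** One component per case, with counts reconstructed
  where the published values pin them down (17 pneumonia cases in Monteny
  from 94% = 16/17 with CI 71–100; 3 meningitis cases in Thompson from
  100% with CI 29–100 and the dropped-item 67% = 2/3) and documented
  synthetic choices elsewhere.
* **Ages** from a log-normal fit to the printed mean and range, truncated to
  the range; the fit (`sdlog = log(max/min)/6`, mean-matched `meanlog`) is
  this package's choice and is recorded in each profile.
* **Recorded-variable inventories** chosen to reproduce the published
  eligibility pattern — FSDT validated in 5 datasets, pneumonia rule in 5,
  meningitis rule in 3, YOS in 3, NICE in 4, NHG in 5 — including the
  specific facts stated in the source (Bleeker lacks diarrhea; Brent lacks
  only nuchal rigidity among the meningitis items and the Yale
  reaction-to-parent item; Oostenbrink records meningeal signs but no
  clinician gut-feeling variable). The exact inventories are otherwise not
  published and are this package's reconstruction.
* **One calibration target per dataset**: a published sensitivity paired
  with a specificity reconstructed from the printed false-positive fraction
  or NLR (e.g. Monteny FSDT 90% with specificity 213/486 from "54% false
  positives"; Oostenbrink meningitis 96% with specificity 0.04/0.1 from
  NLR 0.1). With `k` items independent given disease status and equal
  per-item rates, `calibrate_any_of()` inverts the any-of operating
  characteristics in closed form: `p_pos = 1 − (1 − sens)^(1/k)`,
  `p_neg = 1 − spec^(1/k)`. For the FSDT the targets are first corrected
  for the intrinsic age item, which fires with the age-window mass `q`
  independently of disease: the four clinical items are calibrated to
  `1 − (1 − sens)/(1 − q)` and `spec/(1 − q)`. This is also why Thompson is
  calibrated on its pneumonia-rule pair (27%, specificity 0.9125): an FSDT
  specificity of 0.96 is unattainable when age is independent of disease,
  because the age item alone fires in more than 4% of controls there.
* **Missingness**, MCAR per variable, with vital-sign rates placed inside
  the printed cross-dataset ranges (temperature 0–18%, heart rate 2–48%,
  respiratory rate 15–53%) and small (2–3%) rates on selected rule items.
  MCAR keeps complete-case estimates unbiased, which the recovery check
  relies on; an MNAR option (missingness odds multiplied for cases) exists
  for robustness experiments, because routinely collected clinical data are
  unlikely to be missing at random.

The generator deliberately does **not** reproduce: the joint dependence of
features beyond disease conditioning (items are conditionally independent,
so co-occurrence patterns like "pale *and* mottled" are not realistic); age-
or season-dependent symptom rates; the non-calibrated rules' exact published
operating characteristics (they emerge from documented default
conditionals); or any real child's record. Passing tests therefore
demonstrate that the *pipeline machinery* is correct under the stated
generative assumptions — not that the rules would reproduce their published
accuracy on new clinical data.

## Parameter recovery and problem sizes

Generator correctness is assessed as parameter recovery: for each preset,
datasets are regenerated at n = 10,000 (components scaled proportionally)
over 20 seeds, the calibrated rule is applied through the full pipeline, and
the *seed-averaged* sensitivity and specificity must lie within 3
exact-binomial standard errors (at single-replicate size) of the targets.
The seed average is the package's definition of recovery because it tests
calibration bias directly; individual replicates fluctuate by construction
with standard deviation of one such SE, so a per-replicate criterion over
hundreds of draws would fail occasionally on correct code. Interval
calibration is checked separately: across 200 replicates of a
2,000-record low-prevalence preset, the Clopper–Pearson CIs must contain the
calibration targets in at least 93% of replicates, and exact enumeration
over the binomial support verifies coverage at or above the nominal 95%.

Test problem sizes were chosen so the whole suite runs in well under a
minute of simulation time: exhaustive truth tables up to 2^8, exact-interval
oracle comparisons for all x ≤ n ≤ 30, AUC pair-counting at n ≤ 12, and the
recovery/coverage scales above.

## Numerical and degenerate-input choices

* z is fixed at 1.96 for 95% intervals (matching the published bounds);
  other levels use the normal quantile.
* Zero cells: likelihood ratios add 0.5 to all four cells only when a zero
  cell occurs, and flag the estimate; dumbbell points inherit the flag and
  the plot annotates them.
* Degenerate tables (an empty disease class) are flagged at construction
  and refuse interval estimation; the pipeline records such cells as
  `degenerate` rather than failing the whole grid.
* Wald bounds are clipped to [0, 1]; Clopper–Pearson bounds are exact at
  x = 0 and x = n by convention (0 and 1).
* Display rounding is half-away-from-zero: prevalences to one decimal,
  sensitivity/specificity to integers, likelihood ratios to one decimal —
  the conventions of the published tables.
* AUC for a dichotomous rule is reported as the single-threshold trapezoid
  `(sens + spec)/2` and labelled as such; the rank (Mann–Whitney, mid-rank
  ties) statistic is used for the Yale sum score.

## Open design decisions

Where the source material left room, the package decides and documents:

* **Positive-fraction denominator.** "Percentage testing positive" is
  reported over evaluable records, with the all-records denominator also
  available (`positive_fraction_total`), since the published denominators
  are ambiguous.
* **Yale positivity** is strict `> cutoff`, following the wording "a score
  of greater than 10"; a ≥ reading can be obtained by passing cutoff − 1.
* **CI-overlap comparisons** (age-subgroup and reduced-rule analyses) use
  closed intervals, so touching bounds count as overlapping — the
  conservative reading of "similar 95% CIs".
* **Age windows** are `[lo, hi)` in months ("3 to 36 months" → `[3, 36)`).
* **Determinism.** Identical inputs and configuration produce byte-identical
  JSON reports; the run timestamp is kept in the in-memory object but left
  out of the serialized report by default.

## Known limitations

The validation is only as faithful as the reconstructions it rests on: the
recorded-variable inventories, component-outcome splits and calibration
specificities are inferred from printed summaries, not from the source
data. The conditional-independence generative model understates real-world
item correlation, which typically makes any-of rules *look* slightly better
calibrated than they would be on real data. No meta-analytic pooling across
datasets is performed (deliberately, matching the source analysis), and the
non-validatable rules (a dehydration rule, a second pneumonia rule requiring
parental concern, a second meningitis rule) are out of scope.
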