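---
title: "Preparing prescription records as time-varying drug exposure: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Preparing prescription records as time-varying drug exposure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rxprep)
library(data.table)
```

## The problem

Primary-care electronic health records hold prescription *issues*, not
exposure. A therapy record says that on some date a product was issued with
a total quantity (`qty`), a numeric daily dose (`ndd`), a prescriber-entered
duration (`numdays`) and sometimes a database-derived duration
(`dose_duration`). It does not say when the patient stopped taking the
drug; the duration fields are very sparsely populated and all four fields
contain clinically implausible entries. Before any pharmacoepidemiological
analysis — say, a hazard ratio for cardiovascular events under oral
hypoglycaemic or glucocorticoid therapy — the raw records must be cleaned,
given stop dates, deduplicated, and stitched into episodes of *current
exposure*. Every one of those steps requires an assumption, each assumption
is defensible, and published studies rarely report which one was made.

rxprep makes the assumptions explicit. The preparation is organised as ten
ordered decision nodes in three steps:

* **Step A — cleaning (nodes 1–5).** Implausible and missing `qty`
  (nodes 1–2), implausible and missing `ndd` (nodes 3–4), implausible
  duration fields (node 5), each judged against per-product clinical
  plausibility bounds.
* **Step B — stop dates (nodes 6–7).** Node 6 chooses the duration source:
  `numdays`, `dose_duration`, `qty/ndd`, or a reconciliation of whichever
  candidates are available within a tolerance of x days. Node 7 handles
  records still missing a stop date; whatever is left unresolved after
  node 7 is dropped.
* **Step C — episodes (nodes 8–10).** Same-day duplicates within a product
  (node 8), overlapping prescriptions within a drug class (node 9), and
  short gaps between episodes (node 10).

The ten menus hold 54 options in total; one option per node defines a
*pathway*, a complete preparation recipe serialised as a token string such
as `"1b,2a,3b,4b,5b,6c,7b,8c,9a,10b(15)"`. The pathway space is the
Cartesian product of the menus:

```{r registry}
reg <- default_registry()
reg
count_pathways(reg)
```

Because assumptions interact with the missingness structure of the data,
different pathways can move the downstream effect estimate. The package
therefore treats preparation itself as an object of study: a
two-stage sensitivity experiment runs a sample of random pathways, then a
pre-specified primary pathway plus every one-at-a-time perturbation of it,
and compares the resulting hazard ratios and standard errors.

## Conventions and numerical choices

These choices are deliberate and fixed; all are covered by tests.

* **Dates are integer day offsets** from an arbitrary epoch; there is no
  time of day. All intervals are half-open `[start, stop)`: a one-day
  prescription has `stop = start + 1` and length `stop - start`.
* **Rounding is half-up to whole days** (`round_half_up()`), everywhere a
  fractional duration or a mean date arises. The mean of two dates an odd
  number of days apart is the later middle day. A derived duration of zero
  days (e.g. `qty/ndd` rounding to 0) becomes missing: a prescription must
  cover at least one day.
* **Plausibility bounds are inclusive**; a value equal to a bound is
  plausible. Products missing from the plausibility table are treated as
  fully plausible, with a warning.
* **Imputation snapshots are per node.** Population and patient means and
  carry-forward donors are computed once from a frozen snapshot of the
  node's input, restricted to plausible values, so results do not depend
  on the order records are visited and every Step A operation is
  idempotent. "Population" means the supplied dataset, per product code;
  when a mean-imputing option finds no donors it falls back to the product
  default from the plausibility table, and a carry-forward option with no
  prior prescription leaves the value missing.
* **Node 7 does not cascade.** The patient-mean (7b) and carry-forward
  (7e) options use exactly their own donor pool — durations observed among
  the patient's same-product records that resolved a stop date at node 6.
  When no donor exists the stop date stays missing and the record is
  dropped, as the framework's drop rule prescribes. Cascading to a
  population or default fallback would quietly rescue every record and
  erase the very difference between stop-date sources that the sensitivity
  analysis is designed to expose.
* **Node 6d tie-break.** With three candidates the rule takes the mean of
  the closest pair if that pair lies within x days. When two pairs are
  equally close, the pair containing the `qty/ndd` candidate wins (it is
  by far the best-populated source in this kind of data); the remaining
  tie is broken by a fixed pair order. Symmetry under permutation of the
  candidates therefore holds exactly on tie-free configurations and is
  tested as such.
* **Node order is fixed** at 1 through 10; no option may inspect a later
  node's choice. Gaps are bridged (node 10) before clipping to follow-up.
* **Strict inequalities**: an overlap means the later start is strictly
  before the running stop; a gap is bridged by `10b(x)` only when it is
  strictly shorter than x days.
* **The audit ledger** records, for every node, how many records came in,
  were modified, set missing, or removed. Rows absorbed by a collapse or
  merge (nodes 8–10) are counted as removed so that
  `records_out = records_in - records_dropped` holds at every node;
  records are *discarded for cause* only at node 7 (unresolved stop dates)
  and node 9e.

## The synthetic cohort generator

No real EHR extract ships with the package, so the generator produces
cohorts whose structure mimics the raw layout while every quantity of
interest is known exactly. For each patient it draws a follow-up window,
a therapy initiation day, and a course plan under one of two regimes:
`"continuous"` (long-term repeat prescribing: mostly 28-day scripts with
small refill gaps) or `"intermittent"` (1–4 short courses separated by
months). Prescription fields are generated *consistently* — `numdays` and
`dose_duration` equal the true duration, `qty = duration × ndd` — and the
ground-truth exposure (the union of true prescription intervals) is stored
alongside. Corruption is applied afterwards: each field is masked
independently at the regime's missingness rate, and a small fraction of the
surviving values is replaced with out-of-bounds ones. The regime defaults
for field missingness are the rates observed in UK primary-care therapy
data for the two exemplar drug families: 12.5% `ndd` / 97.2% `numdays` /
99.9% `dose_duration` in the continuous regime, and 50% / 97% / 99.2% in
the intermittent one.

Outcome events are drawn from an exponential model whose hazard is
`baseline_hazard × exp(log_hr)` during true exposure and `baseline_hazard`
otherwise (defaults: 2 × 10⁻⁴ events per person-day and a true hazard
ratio of 2). This piecewise-constant model is the simplest one consistent
with the proportional-hazards analysis downstream, and makes the Cox
partial-likelihood estimand equal the generating log hazard ratio.

Two generator choices deserve emphasis:

* **Product codes are pack-level granular.** Each prescription draws its
  code uniformly from the class's twelve codes, reflecting product
  dictionaries in which every brand, strength and pack size is a distinct
  code. The visible consequence — tiny patient-by-product donor pools for
  patient-level imputation — is exactly what makes the sparse duration
  sources (`numdays`, `dose_duration`) so destructive when chosen as the
  stop-date source.
* **Missingness is independent per field and record.** Only marginal rates
  are emulated; no correlation structure between fields, practices or
  calendar time is modelled. Passing tests therefore demonstrate correct
  mechanics and calibration under independent missingness, not robustness
  to the structured missingness of real EHR data.

```{r generate}
cfg <- generator_config(n_patients = 200, seed = 1)
cohort <- generate_cohort(cfg)
sapply(cohort$therapy[, .(qty, ndd, numdays, dose_duration)],
       function(x) round(mean(is.na(x)), 3))
```

## Downstream analysis

`split_person_time()` turns a prepared timeline into counting-process rows
alternating between exposure states, censored at the event; the event is
attributed to the interval *ending* at the event date, matching the
`Surv(start, stop]` risk-set convention. `fit_exposure_model()` fits an
unadjusted Cox model with the Breslow tie correction (day-granular data
guarantee ties) and reports a Wald 95% CI on the log scale. Non-estimable
situations — no events, no person-time in a contrast level, a monotone
likelihood — are reported as `estimable = FALSE`, never as an error, so a
sensitivity experiment always completes.

Outlier flagging in `summarize_results()` uses the standard 1.5 × IQR rule
plus optional absolute thresholds supplied by the caller; no dataset-specific
cut-off is hard-coded.

```{r experiment, eval = FALSE}
res <- sensitivity_experiment(
  cohort$therapy, default_registry(), default_primary_pathway(),
  k_random = 50, seed = 2,
  plausibility = cohort$plausibility, followup = cohort$followup)
summarize_results(res)
plot(res)
```

## The primary pathway and problem sizes

The package's default primary pathway —
`r format_pathway(default_primary_pathway())` — sets implausible values
missing (1b, 3b, 5b), leaves missing `qty` alone (2a), imputes missing
`ndd` from the patient's own plausible values (4b), derives stop dates from
`qty/ndd` (6c; the least-missing source), imputes missing stop dates from
the patient's mean duration for the product (7b), sums same-day duplicates
(8c), stockpiles overlaps (9a) and bridges gaps under 15 days (10b(15)).
It is a reasonable reference recipe, not a recommendation; the point of
the framework is that the choice is explicit and perturbable.

The shipped tests and the acceptance script exercise the full pipeline on
2000-patient cohorts (the scale at which the Cox SE is small enough for
the comparisons to be meaningful), 50 random pathways plus the 1 + 44
one-at-a-time stage, and 20 replicates for the parameter-recovery check.
These sizes are the package's own choices and can be scaled up freely.

## Known limitations

* Dose trajectories are out of scope: the output is binary
  exposed/unexposed per drug class, with no dose quantification.
* Concurrent exposure to multiple classes is not modelled as a separate
  state; overlapping episodes across classes are truncated with a warning
  when person-time is split.
* The printed pathway count is the raw product of the menus; frameworks
  that restrict option applicability conditionally would count fewer.
* The generator does not emulate free-text dosing instructions,
  practice-level clustering, competing risks, or informative censoring.
* Node order is fixed; the framework cannot currently express
  researcher-specified preference orders among duration sources.
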