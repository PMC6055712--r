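# rxprep

Transparent preparation of raw prescription records into time-varying
binary drug-exposure episodes, and quantification of how the preparation
assumptions move downstream hazard-ratio estimates.

## The problem

Primary-care research databases record prescription *issues*: a product
code, an issue date, a total quantity (`qty`), a numeric daily dose
(`ndd`), a prescriber-entered duration (`numdays`) and a sparsely derived
duration (`dose_duration`). They do not record when exposure stopped, and
the fields contain missing and clinically implausible values. Turning this
into the time-varying exposed/unexposed covariate a survival analysis
needs takes a long chain of small decisions — and different, equally
defensible choices can change the estimated hazard ratio.

rxprep implements that chain as an explicit decision framework:

* **Step A** (nodes 1–5): clean implausible/missing `qty`, `ndd` and the
  duration fields against per-product plausibility bounds;
* **Step B** (nodes 6–7): derive a stop date per prescription
  (`start + numdays`, `start + dose_duration`, `start + qty/ndd`, or a
  reconciliation of the available candidates within x days), then impute
  or drop records still missing one;
* **Step C** (nodes 8–10): collapse same-day duplicates, resolve
  overlapping prescriptions (stockpiling, truncation, union, duration
  summing, or dropping), and bridge short gaps between episodes.

The ten nodes offer 54 options in total; one option per node is a
*pathway* — a complete, serialisable preparation recipe such as
`"1b,2a,3b,4b,5b,6c,7b,8c,9a,10b(15)"`. The default registry spans
5⁸ × 7 × 7 = 19,140,625 distinct pathways. Every run produces an audit
ledger of per-node record counts (`records_out = records_in −
records_dropped` at every node), and a two-stage sensitivity experiment
(random pathways, then one-at-a-time perturbations of a primary pathway)
fits an unadjusted time-varying Cox model
(`Surv(start, stop, event) ~ exposure`, Breslow ties, Wald 95% CI) per
pathway. A seeded synthetic cohort generator with known ground-truth
exposure and outcome hazards makes the whole pipeline testable without
any real data extract.

## Worked example

The package ships a 12-record example (two patients, three products)
whose preparation under the default primary pathway is fully
hand-traceable:

```r
library(rxprep)
library(data.table)

therapy      <- fread(system.file("extdata", "therapy_example.csv",      package = "rxprep"))
plausibility <- fread(system.file("extdata", "plausibility_example.csv", package = "rxprep"))
followup     <- fread(system.file("extdata", "followup_example.csv",     package = "rxprep"))

res <- run_pathway(therapy, default_primary_pathway(), plausibility,
                   followup[, .(patient_id, entry, exit)])
res$episodes
#>    patient_id drug_class start  stop
#> 1:         p1       drug     0   139
#> 2:         p1       drug   210   238
#> 3:         p2       drug    10    66
#> 4:         p2       drug   100   128
#> 5:         p2       drug   350   365
```

Patient `p1`'s first five prescriptions (one with an implausible
quantity set missing at node 1b and a stop date recovered at node 7b, a
same-day pair summed at node 8c, one overlap stockpiled at node 9a) fuse
into a single episode `[0, 139)` once the sub-15-day gaps are bridged at
node 10b(15); a donor-less record is dropped at node 7, visible in the
ledger:

```r
res$ledger[node %in% c("7", "8", "10")]
#>    node records_in records_modified records_set_missing records_dropped records_out
#> 1:    7         12                1                   0               1          11
#> 2:    8         11                1                   0               1          10
#> 3:   10         10                2                   0               5           5
```

On a synthetic cohort, the two-stage sensitivity experiment shows the
framework's central finding — most assumptions barely matter, but the
stop-date source (node 6) does, because `numdays` and `dose_duration`
are almost always missing:

```r
coh <- generate_cohort(generator_config(n_patients = 500, seed = 42))
res <- sensitivity_experiment(coh$therapy, default_registry(),
                              default_primary_pathway(), k_random = 10,
                              seed = 43, plausibility = coh$plausibility,
                              followup = coh$followup)
summarize_results(res)
#> Pathway results: 55 (non-estimable: 2)
#>  median HR 1.529, median SE 0.240, IQR(HR) 0.120
#>  outlying pathways:
#>                               pathway        hr        se
#> 1: 1a,2b,3a,4a,5d,6b,7c,8b,9d,10b(60) 1.1495503 0.2445853
#> 2: 1b,2a,3b,4d,5b,6c,7b,8c,9a,10b(15) 1.2177115 0.2300632
#> 3: 1b,2a,3b,4b,5b,6a,7b,8c,9a,10b(15) 0.3380011 1.0069854
#> 4: 1b,2a,3b,4b,5b,6c,7b,8c,9e,10b(15) 1.2153091 0.2275911
```

The third outlier is the primary pathway with node 6 switched to 6a
(stop dates from the 97%-missing `numdays`): most records drop and the
SE quadruples. The two non-estimable pathways use 6b
(`dose_duration`, ~99.9% missing).

A thin command-line wrapper over these functions is installed at
`system.file("scripts", "rxprep", package = "rxprep")`, with
`simulate`, `prepare`, `enumerate`, `sample` and `sensitivity`
subcommands.

## Documentation

The methods vignette
(`vignettes/drug-exposure-preparation.Rmd`) documents the interval and
rounding conventions, the per-node snapshot semantics of imputation, the
node-6d tie-break, what the synthetic generator does and does not
emulate, and the package's known limitations.
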