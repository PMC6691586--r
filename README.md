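# sigbar

Patient-specific signaling barcodes from surprisal analysis of proteomic
profiles.

## The problem

Bulk proteomic panels (e.g. reverse phase protein arrays profiling ~200
cancer-related proteins and phosphoproteins across thousands of tumors) show
enormous inter-tumor heterogeneity, yet clustering tumors into a handful of
types discards exactly the patient-specific differences that matter for
choosing a drug combination.  sigbar implements the opposite strategy:
describe *every* sample individually by the small set of altered protein
subnetworks — *unbalanced processes* — it harbors, and design a drug
combination that hits all of them.

The core model is surprisal analysis.  Measured abundances are decomposed as

    ln X_i(k) = Σ_α G_iα · λ_α(k),      α = 0, 1, 2, ...

fitted by singular value decomposition of the ln-expression matrix
(proteins × samples).  Component α = 0 (largest singular value) is the
balanced steady state; each subsequent component is a candidate unbalanced
process with protein weights `G_iα` and per-sample amplitudes `λ_α(k)`.  The
pipeline then:

1. chooses the number of significant processes `m*` from the plateau of
   per-sample R² convergence curves;
2. thresholds amplitudes (against the pooled noise-component amplitude) and
   weights (against the null orthonormal-column SD `1/√n`) to decide which
   processes are active in which samples and which proteins participate in
   which processes;
3. normalizes each sample's significant amplitudes to a **barcode** in
   {−1, 0, 1}^m\* — the patient-specific signaling signature — and catalogs
   barcode recurrence and rarity across the cohort;
4. assembles each process's participating proteins into a signed subnetwork
   using a protein–protein interaction edge list (STRING-export style),
   ranks druggable hubs by degree × |weight|;
5. designs a per-sample drug combination by greedy weighted set cover so
   that every active process is targeted through one of its top hubs.

A synthetic-data generator with planted ground truth
(`simulate_expression()`) makes every stage testable end to end, and
`score_recovery()` quantifies how well the planted structure is recovered.

## Worked example

```r
library(sigbar)

# a synthetic cohort at the reference conditions:
# 200 proteins x 150 samples, 3 planted processes, SNR 5
sim <- simulate_expression(seed = 1)

d <- surprisal_decompose(sim$expression)
d
#> <surprisal_decomp> 200 proteins x 150 samples, 150 components (0 = steady state)
#>   singular values: 1059, 12.24, 11.04, 10.29, 5.106, ...

m <- select_num_processes(r_squared_curve(d))
m
#> [1] 3

model <- fit_significance(d, m)
model
#> <significance_model> m* = 3, amp threshold ~ 0.4586 (pooled-noise-rms), weight threshold 0.1414

barcodes <- make_barcodes(d, model)
catalog  <- classify_rarity(build_catalog(barcodes))
glance(catalog)
#> # A tibble: 1 × 6
#>   n_samples n_distinct null_fraction n_abundant n_rare n_singleton
#>       <int>      <int>         <dbl>      <int>  <int>       <int>
#> 1       150         23             0         20      9           3

head(tibble::as_tibble(catalog[, c("barcode", "count", "frac", "rarity_class")]), 3)
#> # A tibble: 3 × 4
#>   barcode count   frac rarity_class
#>   <chr>   <int>  <dbl> <chr>
#> 1 -1,1,0     14 0.0933 abundant
#> 2 1,1,0      11 0.0733 abundant
#> 3 1,-1,0     10 0.0667 abundant

score_recovery(sim$truth, d, model)
#> # A tibble: 1 × 7
#>   process_count_error amplitude_cor membership_f1 barcode_accuracy n_matched ...
#> 1                   0         0.965             1            0.973         3
```

Reading the output: the three large post-steady-state singular values (12.2,
11.0, 10.3) stand clear of the noise floor (~5.1); the plateau rule selects
exactly the three planted processes; 150 samples collapse into 23 distinct
barcodes, led by signatures such as `-1,1,0` (process 1 down, process 2 up,
process 3 inactive); and the recovered amplitudes, memberships and barcodes
match the planted truth (|r| = 0.965, F1 = 1, Hamming accuracy = 0.973).

With an interaction edge list and a drug table the same objects feed
`build_subnetwork()`, `rank_hubs()`, and `design_combination()`; the whole
chain (including TSV/JSON/SIF/GraphML exports) is orchestrated by
`run_pipeline()` or the wrapper script `inst/scripts/sigbar-pipeline.R`.

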