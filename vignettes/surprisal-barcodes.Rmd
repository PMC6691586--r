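---
title: "Surprisal analysis of proteomic cohorts: models, thresholds, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Surprisal analysis of proteomic cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sigbar)
```

## The model

sigbar treats a tumor (or cell line) proteomic profile as a thermodynamic-like
system displaced from a balanced steady state by a small number of
constraints.  Each constraint forces a group of proteins to co-vary — an
*unbalanced process*.  Writing $X_i(k)$ for the measured abundance of protein
$i$ in sample $k$, the expansion is

$$\ln X_i(k) \;=\; \sum_{\alpha \ge 0} G_{i\alpha}\,\lambda_\alpha(k),$$

where component $\alpha = 0$ is the steady state and each $\alpha \ge 1$ is a
candidate unbalanced process with protein weights $G_{i\alpha}$ and
sample-specific amplitudes $\lambda_\alpha(k)$.  The expansion is fitted by
singular value decomposition of the $\ln$-expression matrix:
$G$ holds the left singular vectors, $\lambda_\alpha = d_\alpha v_\alpha$ the
scaled right singular vectors, and the steady state is the component with the
largest singular value, following standard surprisal-analysis practice.  The
expansion is exact when all components are kept; the scientific content is in
deciding how many components carry signal, which proteins participate in each,
and in which samples each process is active.

Some presentations of this expansion write the deviation terms with an
explicit minus sign relative to the steady state.  sigbar stores one
canonical additive form and defines every sign-bearing output (direction of
change, barcode entries) through the *product* $G_{i\alpha}\lambda_\alpha(k)$,
which is invariant under the inherent SVD sign ambiguity.  The remaining
gauge freedom is fixed deterministically: in each component, the weight of
largest magnitude is made positive.

Two further conventions are configurable because the underlying choice is
genuinely open in the literature:

* **Centering.** By default protein rows are *not* mean-centered before the
  SVD; the steady state is then recovered as component 0.  `center = TRUE`
  moves the row means out of the factorization instead.  Both reconstruct
  identically.
* **Amplitude scale.** Amplitudes are $d_\alpha v_\alpha$ (not bare
  $v_\alpha$), so a process's amplitudes carry its singular value.  This only
  rescales thresholds, which are estimated per fit anyway.

## Choosing the number of processes

For each sample, `r_squared_curve()` computes the squared Pearson correlation
between $\ln X(k)$ and the reconstruction truncated after $m$ processes.  The
curves rise and then plateau; components past the plateau behave like noise.
`select_num_processes()` returns the smallest $m$ such that adding process
$m+1$ improves $R^2$ by less than `epsilon` (default 0.005) in at least
`frac` (default 0.95) of samples.  Both parameters are exposed because the
plateau criterion is a convention, not a theorem; the defaults encode "a
process must visibly improve the fit of at least 5% of the cohort".

The absolute threshold `epsilon` interacts with the data's variance scale and
with cohort size.  A useful rule of thumb from the spiked-matrix analysis
below: for an $n \times m$ matrix with per-protein $\ln$-variance $V$ and
noise variance $\sigma^2$, a noise component improves a single sample's $R^2$
by roughly $\sigma^2 s^2_{\text{noise}}/(m\,n\,V)$ with a heavy
($\chi^2_1$-like) upper tail, while a process of amplitude $\lambda$
contributes $\lambda^2/(nV)$.  At the package's reference conditions (200
proteins, 150 samples, $\sigma = 0.2$, $V \approx 1$) the default `epsilon`
separates the two cleanly.  For substantially smaller cohorts the noise tail
crosses 0.005 and the rule over-selects; `epsilon` should then be raised (or
judged from the plotted curves via `plot_r_squared_curves()`).

## Significance thresholds

A process is **active** in a sample when its amplitude exceeds what the noise
components produce: the threshold is `c_amp` (default 2) times the
root-mean-square amplitude pooled over the components beyond $m^*$, which are
noise by construction.  This is a self-contained, data-driven surrogate for
an experimental-error limit: it asks "is this amplitude larger than twice the
typical noise amplitude?".  When no components beyond $m^*$ exist the rule
falls back to a per-process median-absolute-deviation scale with a warning.

A protein **participates** in a process when $|G_{i\alpha}|$ exceeds
`c_w / sqrt(n_proteins)` (default `c_w = 2`).  A null orthonormal column of
random direction has entries of standard deviation $1/\sqrt{n}$, so this is a
closed-form two-sided $\approx 2$ SD cut — chosen over an elbow heuristic
because it is testable and parameter-free given `c_w`.

Activity is deliberately thresholding, not hypothesis testing: no multiple
testing machinery is attached, mirroring how such signatures are used in
practice.

## Barcodes and catalogs

Each sample's signature is its **barcode**: the vector over the $m^*$
significant processes with entry $\operatorname{sign}(\lambda_\alpha(k))$
where the process is active and 0 otherwise.  Positive and negative
activations of the same process are distinct signatures (the sign determines
which proteins go up and which down).  The all-zero barcode is the *null
barcode*.  `build_catalog()` groups identical barcodes with deterministic
ordering (count descending, then lexicographic), and `classify_rarity()`
applies the recurrence classes used for cohort description: *abundant*
(≥ 1% of the cohort by default), *rare* (≤ 5 samples), *singleton* (exactly
one).  The flags overlap by design — a singleton is also rare — and
`rarity_class` reports the most specific label.

Incremental cohort addition (`add_cohort()`) re-decomposes the combined
matrix rather than projecting new samples onto frozen weights, because the
scientific question is whether the *same* processes emerge; the
correspondence report (greedy maximum-|correlation| matching of weight
columns over the shared protein vocabulary) quantifies exactly that.  A
projection mode is a possible extension but is not what the workflow
validates.

## Subnetworks, hubs and therapy design

Participating proteins of a process are assembled into a subnetwork by
restricting a protein–protein interaction edge list (STRING-export style,
default confidence cutoff 700) to the member set.  Antibody-level ids are
first mapped to gene symbols through a user-supplied alias map; unmapped
antibodies remain as flagged isolated nodes rather than being dropped —
absence of interaction evidence is not absence from the process.

Hubs are ranked by *degree × |weight|*: a good drug target is both central
among the co-varying proteins and strongly loaded on the process.  The
product is one reasonable operationalization of "major targetable hub";
degree-only and weight-only rankings are available via `score_by` for
sensitivity analysis.

Therapy design follows the principle that **every active process must be
hit**.  Drug candidates per process are drugs targeting one of its top-`k`
hubs (default `k = 3`).  The per-sample combination is a greedy weighted set
cover — repeatedly take the drug covering the most still-uncovered processes,
ties broken by summed hub score then drug name — which is deterministic,
always completes the cover when one exists, and is within the standard
$1 + \ln m$ factor of optimal (verified against exhaustive search in the test
suite; an exhaustive mode exists for small active sets).  The optional
`boost_factor` rule demands double coverage for processes whose amplitude is
at least that factor above the cohort median for the process, encoding the
observation that exceptionally strong processes may need an extra drug.
Candidate lists are always reported alongside the chosen set, since the final
pick among alternatives is a clinical judgment, not an algorithmic one.

## The synthetic-data generator

`simulate_expression()` generates positive abundance matrices whose natural
log is the model above with known ground truth:

* **Steady state**: per-protein baseline $\ln$-levels $N(6, 1)$ times a
  per-sample factor $1 + N(0, 0.02^2)$ — a rank-1 term that dominates the
  spectrum, as in real cohorts.  The baseline SD of 1 (about $e^2$-fold
  between ±1 SD proteins) matters: it sets the variance scale against which
  the plateau rule's absolute `epsilon` is interpreted (see the consistency
  argument above).
* **Planted processes**: sparse unit-norm weight columns (default 5% of
  proteins per process) with equal-magnitude, random-sign support entries, so
  every planted member is unambiguously above or below any weight threshold.
  Supports are disjoint by default, making the columns exactly orthogonal and
  membership truth crisp; `overlap = TRUE` draws overlapping supports and
  Gram–Schmidt-orthogonalizes, for stress tests.
* **Activity**: process $\alpha$ is active in a stratified
  $\texttt{activity\_rate} \cdot \texttt{activity\_decay}^{\alpha-1}$
  fraction of samples (defaults 0.95 and 0.8), each sample capped at 4 active
  processes.  Decaying prevalence mirrors real cohorts, where the leading
  process recurs in about half the samples and later ones are progressively
  rarer — and it is what makes the processes identifiable: equal prevalences
  give nearly degenerate singular values, and the SVD can only recover the
  planted factors up to rotation inside the degenerate subspace.
* **Amplitudes**: zero-inflated — exactly 0 when inactive, random-sign
  magnitudes $|N(\text{amp\_scale}, (\text{amp\_scale}/10)^2)|$ when active.
  Signs are assigned by a greedy balancing pass that keeps the planted
  amplitude rows near-orthogonal (and sum-balanced against the steady state).
  Orthogonal constraints are the identifiability premise of the SVD fit;
  i.i.d. signs would leave $O(\sqrt{m})$ cross-correlations between rows that
  rotate the recovered components.
* **Noise**: i.i.d. $N(0, \sigma^2)$ on the $\ln$ scale, with
  `amp_scale / noise_sd` the signal-to-noise ratio (default 5).

What the generator does **not** emulate: antibody-specific noise levels,
spatial/batch effects, heavy-tailed outliers, missingness patterns, or
correlated (non-orthogonal) biological processes.  Passing tests on this
generator therefore demonstrate the pipeline's correctness and its behavior
under the model's own assumptions — not robustness to the full messiness of
real array data.

### What recovery can and cannot achieve

For a spiked matrix, the attainable correlation between an estimated and a
planted amplitude row is approximately
$\sqrt{1 - \sigma^2 n / s_\alpha^2}$ with $s_\alpha^2 \approx
m\,p_\alpha\,\text{amp\_scale}^2$ ($p_\alpha$ the activation rate).  At SNR 5
with 200×150 this means every process needs $p_\alpha \gtrsim 0.55$ to clear
$|r| = 0.95$ — which is why the default activation rates are high.  Rarely, a
noise realization bridges two processes whose singular values are close and
mixes them noticeably in a single replicate; the validation criteria are
therefore formulated as means over 20 replicate cohorts, which are stable.

## Problem sizes used in validation

The reference conditions for the packaged validation (test suite and
`scripts/acceptance.R`) are 200 proteins × 150 samples with three planted
processes at SNR 5, 20 replicate cohorts per check; null controls use the
same shape with no planted processes; combinatorial components (catalogs,
induced subnetworks, hub ranking, set cover) are checked against brute-force
oracles on 100–200 random small instances.  These sizes keep every check
sharp while the whole suite runs in about a minute.

## Numerical and degenerate-input choices

* Reconstruction uses the exactness of the SVD; the full-sum identity is
  asserted to $10^{-8}$ relative Frobenius error in every validation run.
* $R^2$ against a zero-variance reconstruction (or observed column) is
  defined as 1 if the residual is zero and 0 otherwise, with a warning.
* Ties are broken deterministically everywhere: hub ranking by |weight| then
  protein id; catalog rows by count then barcode string; drug choice by
  coverage, summed hub score, then name.  Identical inputs give identical
  outputs, including across sample permutations (up to the permutation).
* Raw-scale input must be strictly positive; `log2` input is converted to
  natural log once at load ($\times \ln 2$).  Missing values are rejected
  unless per-protein median imputation is explicitly requested, because
  imputation changes the decomposition and should never happen silently.
* Protein ids match exactly; antibody↔gene reconciliation is only ever done
  through the explicit alias map.

## Known limitations

* The plateau rule's `epsilon` is an absolute $R^2$ gain; cohorts much
  smaller than the reference conditions need a larger `epsilon` (see above).
* Activity calls are threshold-based; no error control in the
  multiple-testing sense is claimed.
* Amplitude recovery degrades gracefully but measurably for processes active
  in less than roughly half the cohort at SNR 5 (see the spiked-model bound).
* The therapy stage is a coverage formalism over a user-supplied drug table;
  it models neither dose, toxicity, nor drug–drug interaction.
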