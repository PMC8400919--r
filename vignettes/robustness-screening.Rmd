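---
title: "Robustness screening of extraction protocols with pbmetab"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Robustness screening of extraction protocols with pbmetab}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pbmetab)
```

## Scope and model

`pbmetab` covers the computational side of selecting and stress-testing a
metabolite extraction protocol for untargeted LC-MS: preprocessing of peak
lists into a feature table, the feature-quality cascade, extraction-method
comparison, and Plackett–Burman robustness screening analysed by
hierarchical linear modelling. Wet-lab steps, raw spectral parsing,
chromatographic peak picking and metabolite annotation are out of scope;
the package starts from centroided per-sample peak lists (m/z, retention
time, abundance) in delimited text.

### Plackett–Burman screening

For up to $n-1$ two-level factors a Plackett–Burman design needs $n$ runs,
$n$ a multiple of 4. `generate_pb_matrix()` builds the smallest such design
by cyclic rotation of the standard generating row plus an all-minus row;
every column is balanced and all column pairs are orthogonal, which
`validate_design()` verifies by exhaustive dot products over the factorial
runs. The design estimates main effects only — interactions are assumed
negligible, the standard screening assumption. A *dummy* factor (a column
assigned to no real protocol change) should be included: its fitted
coefficient estimates the error level and calibrates the reading of the
real factors. Centre-point runs (all factors at their nominal level) are
added with `add_centre_points()`; they carry no contrast information, so
they leave effect estimates untouched in the noiseless limit and only
tighten intercept and residual-sd estimates, but they replicate the nominal
protocol and thereby gauge measurement uncertainty.

The package ships a 15-run worksheet (`table1_design()`) for ten extraction
factors — solvent volumes, vortexing and centrifugation times, evaporation
temperature, reconstitution volume — plus a dummy, with 12 factorial runs
and centre points at ordinal positions 6, 10 and 15. The worksheet is a
sign-flipped variant of the standard cyclic 12-run design (its corner row
is all-plus rather than all-minus); since balance and orthogonality are
invariant to sign flips and row/column permutations, validation checks
those properties rather than cell-by-cell identity with the generator's
output. One caveat is preserved as printed: the first vortexing factor is
labelled minutes but its levels (165/180/195) are plausibly seconds; the
numbers are kept exactly as transcribed.

### The effect model

Robustness is quantified on natural-log abundances. With coded levels
$x_{if} \in \{-1, 0, +1\}$,

$$y_{mi} = \alpha_m + \sum_f \beta_f x_{if} + \varepsilon_{mi},
  \qquad \varepsilon_{mi} \sim \mathcal N(0, \sigma)$$

is the pooled variant: one coefficient per factor shared by all
metabolites, one free intercept per metabolite. The per-metabolite variant
lets each metabolite respond individually with partial pooling,
$\beta_{mf} \sim \mathcal N(\beta_f, \tau_f)$; as $\tau_f \to 0$ it
collapses to the pooled model. The pooled model is the appropriate default
when metabolites broadly share a trend; the hierarchical variant quantifies
how much they do not, without the multiple-comparisons burden of fitting
thousands of separate regressions.

The natural log is used because the conventional reading of a coefficient —
$\beta = 0.1$ is "a 10% abundance increase per unit coded-level step" — is
the small-coefficient linearisation of $e^{\beta}$;
`interpret_coefficient()` returns $100\beta$ and its documentation notes
the exact change is $(e^{\beta}-1)\times100\%$. Coded levels are used as
regressors exactly as designed, not rescaled physical units, so a
coefficient always means "per level step low→centre or centre→high".

### Estimation

All fitting is implemented in the package:

* **Pooled, MAP (default).** Weakly-informative zero-centred priors:
  $\mathcal N(0, 1)$ on each $\beta_f$, half-$\mathcal N(1)$ on $\sigma$,
  flat on intercepts (scales configurable; `Inf` gives a flat prior).
  Centring the design columns decouples intercepts from coefficients, so
  the joint mode reduces to a ridge solve for $\beta$ alternated with a
  closed-form scalar update for $\sigma$; uncertainties are Laplace
  (inverse-Hessian) standard deviations. The fit is exactly deterministic.
  With flat priors on an orthogonal design the estimates equal the
  least-squares projection $\beta_f = \sum_i x_{if}\bar y_{\cdot i} /
  \sum_i x_{if}^2$, which the tests assert to $10^{-6}$.
* **Pooled, Gibbs.** A blocked conjugate sampler (intercepts given
  coefficients; coefficients given intercepts; $\sigma^2$ given both) for
  full posteriors, seeded and reproducible. Conditional conjugacy requires
  an inverse-gamma prior on $\sigma^2$ (vague, IG(0.01, 0.01)) in place of
  the MAP's half-normal; with any usable amount of data the likelihood
  dominates either choice.
* **Per-metabolite.** The model is a linear mixed model with independent
  random slopes, so the metabolite deviations are marginalised analytically:
  $y_m \sim \mathcal N(\alpha_m 1 + X\beta,\; X\,\mathrm{diag}(\tau^2)X' +
  \sigma^2 I)$. Intercepts and population coefficients are profiled out by
  GLS, the $f{+}1$ variance parameters are optimised on the log scale
  (L-BFGS-B) under the half-normal penalties, and per-metabolite
  coefficients are recovered as empirical-Bayes (BLUP) estimates. One test
  cross-checks the population coefficients against `lme4`'s independent
  implementation of the same marginal likelihood.

Numerical notes. Maximum-marginal-likelihood variance components at 15 runs
are biased low (no REML correction is applied; with 12 informative
contrasts per metabolite shared across 11 slope variances, $\sigma$
typically reads ~10% below truth at $\tau > 0$); coefficient estimates are
unaffected. $\tau$ estimates have a noise floor of roughly
$\sigma/\sqrt{12}$ per factor — spreads below the per-factor contrast noise
are not identifiable from one batch. Degenerate designs (a constant factor
column) are rejected before fitting; features missing in any run are
excluded from the model matrix rather than imputed, because 15 runs cannot
support a missingness model, and the exclusion count is reported.

## Preprocessing and the quality cascade

`noise_filter()` removes signals strictly below 200 counts (the
conventional TOF background floor; a peak exactly at the threshold is
kept). `align_features()` groups peaks across samples by greedy centroid
clustering in descending abundance order: a peak joins a feature when it is
within 15 ppm in m/z and 0.15 min in retention time of the feature's
abundance-weighted consensus, never contributing two peaks from one sample
to one feature; the best candidate wins by smaller ppm distance, then
smaller rt distance, then lower feature id, and a same-sample runner-up
seeds a new feature. Tolerance tests are against the consensus, not
member-vs-member; this convention is fixed and documented since vendor
tools differ. The abundance-weighted consensus was chosen for robustness to
low-signal stragglers. Missing abundances are explicit `NA`s, never zeros.

`annotate_adduct_groups()` ties co-eluting features whose mass difference
matches a pairwise difference of the ionisation mode's adduct masses
(positive: H⁺, Na⁺, K⁺, NH₄⁺, water loss; negative: H⁻, HCOO⁻, Cl⁻, water
loss), closing groups transitively. Annotation is informational only —
abundances are never merged, because the collapsing rules of vendor
deconvolution tools are not reproducible from their documentation.

The quality cascade then applies, in order: **blank exclusion** (any
non-missing abundance in any blank discards the feature outright — no
fold-change ratio, matching the outright-discard convention),
**all-replicate presence** (a feature counts as extracted by a method only
if detected in every one of its replicates), and **CV classification**
(sample sd over mean, $n-1$ denominator, strictly below 20% marks a
reproducible feature; 20% is the conventional quality threshold in
untargeted metabolomics). Stage counts are non-increasing by construction
and the whole cascade is tested against brute-force enumeration on small
tables. CV is computed on raw abundances (its conventional definition),
and mean CV per method is averaged over the extracted (all-replicate)
features, excluding the none-defined cases.

Method comparison reports, per method: extracted features, reproducible
features, mean CV, and exclusive UpSet-style intersection counts in which
each feature counts toward exactly the subset of methods that detected it,
so counts sum to the union size (asserted on every call).

## The synthetic-data generator

Because studies of this kind rarely deposit raw data, the generator is a
first-class module: every pipeline stage is validated against data with
recorded ground truth. It emulates:

* log-normal baseline abundances (default mean $\log 5\times10^4$, sd 1 on
  the log scale — a realistic signal range sitting well above the 200-count
  noise floor);
* multiplicative replicate noise with log-sd $\sqrt{\log(1+\mathrm{CV}^2)}$
  so a target CV holds exactly in expectation (default 10%, a reproducible
  protocol; method-comparison scenarios use 5–30%);
* design-driven effects acting multiplicatively on the log scale,
  $\mathrm{abundance}_{mi} = \exp(\mathrm{baseline}_m + \sum_f \beta_f
  x_{if} + \mathrm{noise})$;
* blank-only contaminants (default 10) that appear in blanks and study
  samples and carry no design effect;
* stochastic dropout (default 0), uniform m/z jitter within ±5 ppm and rt
  jitter within ±0.05 min (inside half the alignment tolerances, so
  alignment recovery is exact by construction when features are
  well-separated);
* QC injections from one virtual vial, one every four study samples plus a
  closing injection, with quartered noise and an optional exponential drift
  per injection to exercise `qc_drift_check()`.

The batch sizes mirror the screening workflow the package targets: 15
design runs, 2 blanks, QC every 4 injections, 3 replicates per method in
comparisons. What the generator does **not** emulate: chromatographic peak
shapes, isotope envelopes, correlated (structured) noise, retention-time
drift within a batch, censoring of low abundances, or realistic metabolite
identities. Passing tests therefore demonstrate correctness of the
algorithms under the stated noise model, not performance on any particular
instrument's quirks.

Test and example problem sizes (300 features × 15 runs for recovery
checks, 40–200 features elsewhere, 1000 random families for set-count
conservation) were chosen so the full suite completes in well under a
minute while keeping Monte-Carlo margins comfortable — e.g. at 300
features and residual sd 0.2 a planted −0.15 effect is estimated with
standard error ≈ 0.0033, sixty times smaller than the ±0.05 acceptance
band.

## QC drift

Repeated injections from one vial should be flat; `qc_drift_check()` fits a
per-feature least-squares slope of log abundance against injection order
and flags the batch when the median absolute slope exceeds 0.01 per
injection (≈1% signal change per injection — a level at which a 20-sample
batch accumulates ~20% systematic drift, clearly unacceptable). The check
requires at least three QC injections. No drift correction is applied —
the check is a gate, not a normalisation; abundances enter the model
unnormalised by default.

## Design choices that were genuinely open

* **Which generator produced the packaged worksheet** is not derivable;
  equivalence is therefore checked at the level of the screening properties
  (balance, orthogonality), which is what the analysis depends on.
* **Separate fits per LC-MS mode.** Datasets from different
  chromatography/ionisation modes are modelled separately (run the fit per
  feature table); a joint model across modes would entangle incomparable
  abundance scales.
* **Sampler availability.** Full posterior sampling is provided by the
  package's own conjugate Gibbs sampler rather than an external
  probabilistic-programming dependency; the deterministic MAP fit is the
  default backend, and both must satisfy the same closed-form oracle.
* **Pattern alphabet.** Worksheets in circulation mix the typographic minus
  and the ASCII hyphen; both are accepted on input, hyphens are emitted.
* **Run-order randomization** is supported behind an explicit seed but off
  by default: the packaged worksheet's printed order is the reference.

## Known limitations

* Alignment is greedy; pathological peak configurations (chains of peaks
  each within tolerance of the next) can split or chain differently than
  global-optimum clustering would. Results are deterministic and obey the
  stated tolerances, which is the contract.
* The per-metabolite model assumes independent random slopes (diagonal
  $\tau$); correlated factor responses across metabolites are not modelled.
* With 15 runs, $\sigma$ from the marginal-likelihood fit is biased low
  (see above) and $\tau$ has a detection floor; both matter only for
  uncertainty bookkeeping, not for the coefficient point estimates.
* Blank exclusion is binary; a signal-ratio rule (e.g. sample/blank > 10)
  is deliberately not implemented.
* No imputation, batch correction, or QC-based normalisation is performed.
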