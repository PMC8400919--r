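# pbmetab

Plackett–Burman robustness screening for untargeted LC-MS metabolomics.

## The problem

Sample preparation dominates the quality of untargeted metabolomics data:
the choice of liquid–liquid extraction protocol decides how many metabolite
features are captured and how reproducibly they are measured, and small
accidental fluctuations in the protocol (a few µL of solvent, a degree of
evaporation temperature) can silently shift every measured abundance.
`pbmetab` implements the two computational workflows such a study needs:

1. **Extraction-method comparison** — align per-sample LC-MS peak lists into
   a feature table, remove instrument noise and solvent contaminants, and
   compare protocols by extracted-feature counts, reproducible-feature
   counts (coefficient of variation below 20%), mean CV, and exclusive
   UpSet-style overlap counts.
2. **Robustness testing** — screen ten (or any number of) protocol factors
   with a Plackett–Burman design augmented by a dummy factor and
   centre-point replicates, and estimate each factor's effect on metabolite
   abundance with a hierarchical linear model of the log-transformed
   feature table.

It is aimed at analytical chemists and computational metabolomics people who
want the full pipeline — design construction, preprocessing, quality
filtering, modelling, QC drift checks — as tested, scriptable R functions,
plus a synthetic-data generator with recorded ground truth so every stage
can be validated without instrument data.

## The model

A Plackett–Burman design screens up to *n − 1* two-level factors in *n*
runs (*n* a multiple of 4); every coded column is balanced and every pair of
columns orthogonal, so main effects are estimated independently (and
interactions are assumed negligible). A dummy factor — a column tied to no
real protocol change — provides an estimate of error, and centre-point
replicates gauge measurement uncertainty.

Factor effects are estimated from the natural-log feature abundances
`y[m, i]` of metabolite *m* in design run *i* with coded levels
`x[i, f] ∈ {−1, 0, +1}`:

```
pooled:         y[m,i] = alpha[m] + Σ_f beta[f]   · x[i,f] + eps,  eps ~ N(0, sigma)
per-metabolite: y[m,i] = alpha[m] + Σ_f beta[m,f] · x[i,f] + eps,  beta[m,f] ~ N(beta[f], tau[f])
```

The per-metabolite variant partially pools each metabolite's response
toward the population coefficient; when metabolites respond alike
(`tau → 0`) it collapses to the pooled model. On the natural-log scale a
coefficient `b` means a multiplicative abundance change of `exp(b)` per
unit coded-level increase — conventionally read as `100·b` percent for
small `b`, so `beta = −0.15` is an average 15% abundance decrease from a
one-level increase of that factor.

Fitting is done in-package: a deterministic penalized-maximum (MAP) fit
with weakly-informative zero-centred priors and Laplace uncertainties, a
blocked conjugate Gibbs sampler for full posteriors (pooled variant), and
penalized marginal maximum likelihood with GLS profiling for the
per-metabolite variant. With flat priors and an orthogonal design the
pooled estimates coincide with the analytic least-squares projection,
which the test suite verifies to 10⁻⁶.

## Worked example

Screen the packaged 15-run worksheet (ten extraction factors plus a dummy,
three interleaved centre points) on a simulated batch in which the volume
of MTBE truly lowers every abundance by 15% per coded level:

```r
library(pbmetab)

design <- table1_design()
validate_design(design)
#> <design_validation_report> PASS

cfg <- simulation_config(n_features = 300,
                         cv_percent = 100 * sqrt(exp(0.2^2) - 1),  # log-sd 0.2
                         true_beta = c(MTBE2 = -0.15), seed = 1)
sim <- simulate_robustness_experiment(design, cfg)

tab <- drop_blank_features(align_features(lapply(sim$peak_lists, noise_filter)))
tab
#> <feature_table> 300 features x 20 samples (0.0% missing)

qc_drift_check(tab)
#> <qc_drift_report> median |slope| = 0.00213 (threshold 0.01000): PASS

fit <- fit_pooled_model(assemble_robustness_dataset(tab, design))
fit
#> <effect_estimates> pooled model (map), sigma = 0.1964
#>                             factor       beta       sd pct_change
#>                            Metanol -0.0036328 0.003273   -0.36328
#>                              Mtbe1 -0.0047190 0.003273   -0.47190
#>                            vortex1  0.0055358 0.003273    0.55358
#>                              MTBE2 -0.1497284 0.003273  -14.97284
#>                                H20 -0.0011142 0.003273   -0.11142
#>                            Vortex2  0.0003440 0.003273    0.03440
#>                     Centrifugation -0.0052532 0.003273   -0.52532
#>             Volume for Evaporation  0.0004078 0.003273    0.04078
#>            Evaporation Temperature -0.0054904 0.003273   -0.54904
#>  Solvent Volume for Reconstitution -0.0017426 0.003273   -0.17426
#>                       Dummy Factor  0.0015892 0.003273    0.15892
```

The planted −0.15 effect on `MTBE2` is recovered (−0.1497, a −15%
change), every other factor — including the dummy, whose spread estimates
the error level — sits within two standard deviations of zero, and the QC
injections show no signal drift. The blank filter removed the ten
simulated solvent contaminants (310 aligned features → 300).

The comparison workflow is driven the same way (`simulate_method_comparison`,
`summarize_methods`, `intersection_counts`) or from a YAML config via
`run_comparison()` / `run_robustness()`; a thin CLI wrapper lives at
`inst/cli/pbmetab.R`.

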