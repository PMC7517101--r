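# infoens

Statistical analysis of **ensembles of information sources** — collections of
information-theoretic values measured across many elements of a system, such
as the mutual information (MI) of every pairwise connection in a recorded
neural population, of each neuron with a sensory stimulus, or of each gene
pair in an expression panel.

Two questions drive the package:

1. **Is there anything there?** Even a purely noisy system produces strictly
   positive MI estimates from finite data, and some sources will have low
   p-values by chance. The ensemble-level test compares the observed
   information values \{I_i\} (i = 1..n_ens) against the pooled surrogate
   null \{I_null,i,j\} (j = 1..n_MC per source) with a two-sample, two-sided
   Kolmogorov–Smirnov test — sensitive both to ensembles carrying *more*
   information than chance and to ensembles whose information is
   *suppressed* below chance.
2. **Are two ensembles different?** The difference of p-value-weighted mean
   information between two ensembles is tested by randomly permuting
   (value, weight) pairs between the groups, preserving group sizes.

Around these sit the supporting machinery:

- **Per-source surrogate testing.** Each source's null is built by uniformly
  permuting one variable's states (preserving sample size and both
  marginals); the Monte Carlo p-value is the fraction of surrogate values
  ≥ the observed value, floored at `1/(2·n_MC)` when none reaches it.
- **Weighted summaries.** Weights `w_i = −log10(p_i)` (normalized to sum
  to 1) let the more-significant sources dominate the ensemble's weighted
  mean `Ī = Σ w_i I_i`, weighted SEM, and weighted SD.
- **A binary-pair generative model** for calibration and power studies: two
  binary variables with balanced marginals, interaction strength `s ∈ [0,1]`
  (joint-count table `nobs/4 ± Round(nobs·s/4)`), and noise level
  `a ∈ [0,1]` (the fraction of observations whose second variable is
  re-permuted).
- **Sweeps** over `(s, a, n_ens, n_obs)` grids for significance, power, and
  below-null detection studies, plus TSV/JSON serialization and a small CLI.

## Worked example

Simulate a low-noise and a fully noisy ensemble of 40 sources (60
observations each, 100 surrogates per source), summarize both, and compare
them:

```r
library(infoens)
ens_low  <- simulate_ensemble(40, s = 0.4, a = 0.1, nobs = 60, n_mc = 100, seed = 7)
ens_high <- simulate_ensemble(40, s = 0.4, a = 1.0, nobs = 60, n_mc = 100, seed = 8)
summary(ens_low)
#> Ensemble summary [model ensemble (s=0.4, a=0.1, nobs=60)]
#>   sources:            40  (pooled null values: 4000)
#>   weighted mean:      0.1106 bits
#>   weighted SEM:       0.00518 bits
#>   weighted SD:        0.004713 bits (weighted-deviation)
#>   KS vs pooled null:  D = 0.9407, p = 0
summary(ens_high)
#> Ensemble summary [model ensemble (s=0.4, a=1, nobs=60)]
#>   sources:            40  (pooled null values: 4000)
#>   weighted mean:      0.02903 bits
#>   weighted SEM:       0.003894 bits
#>   weighted SD:        0.007761 bits (weighted-deviation)
#>   KS vs pooled null:  D = 0.0545, p = 0.9998
compare_ensembles(ens_low, ens_high, n_perm = 1000, seed = 9)
#> Ensemble comparison: model ensemble (s=0.4, a=0.1, nobs=60) vs model ensemble (s=0.4, a=1, nobs=60)
#>   observed difference in weighted means: 0.0816 bits (A > B)
#>   permutation p-value (directional, 1000 permutations): 5e-04
```

Reading the output: the low-noise ensemble's information values separate
almost completely from their surrogate null (KS D near 1, vanishing p),
while the fully noisy ensemble is indistinguishable from its null (p ≈ 1) —
yet even that null ensemble shows a *positive* weighted mean of ~0.03 bits,
the finite-sample bias that makes the significance machinery necessary. The
comparison p-value of 5e-04 is the permutation floor `1/(2·1000)`: no
permutation produced a difference as large as the observed 0.0816 bits.

Externally computed ensembles (any information measure — entropy, MI,
transfer entropy) enter through `info_ensemble(values, nulls)` or
`read_ensemble("ensemble.tsv")`; see `?read_ensemble` for the file layout.
A command-line wrapper lives at `inst/cli/infoens.R`
(`simulate` / `analyze` / `compare` / `sweep` subcommands).

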