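---
title: "Analyzing ensembles of information sources"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analyzing ensembles of information sources}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(infoens)
```

# The problem

Modern recordings yield information-theoretic values for *many* elements at
once: the mutual information (MI) of every neuron pair in a population, of
every neuron with a stimulus, of every gene pair in a panel. Each single
value is easy to test against a surrogate null; the harder questions are
about the **ensemble**: does the collection of values differ from what a
purely noisy system would produce, and do two such collections differ from
each other? Because MI estimated from finite data is non-negative and
biased upward, even a system with no interactions produces strictly
positive values — naive averaging over an ensemble is therefore
systematically optimistic, and some individual sources will look
significant by chance.

`infoens` addresses this with three pieces: per-source Monte Carlo
p-values from permutation surrogates, an ensemble-versus-null
Kolmogorov–Smirnov (KS) test on the pooled surrogate distribution, and a
permutation test on the difference of p-value-weighted means between two
ensembles.

# The generative model

Each simulated information source is a pair of binary variables $(X, Y)$
observed jointly $n_{obs}$ times, with balanced marginals (half the
observations of each variable in each state). Two parameters control the
data:

| parameter | meaning | domain | default used in demos |
|---|---|---|---|
| $s$ | interaction strength: joint counts are $n_{obs}/4 \pm \mathrm{Round}(n_{obs}\,s/4)$, matched states on the diagonal | $[0,1]$ | 0.4 |
| $a$ | noise level: $\mathrm{Round}(n_{obs}\,a)$ observations are selected uniformly and their $Y$ states randomly permuted among themselves | $[0,1]$ | — |
| $n_{obs}$ | joint observations per source | $\ge 4$, multiple of 4 | 60 |
| $n_{ens}$ | sources per ensemble | $\ge 2$ | 40 |
| $n_{MC}$ | surrogates per source | $\ge 1$ | 100–1000 |

At $s=0$ all four joint states are equally likely; at $s=1$ one variable
determines the other. At $a=0$ there is no noise; at $a=1$ the interaction
is destroyed entirely. `Round()` rounds half-up (0.5 to the next larger
integer) — this is stated explicitly because language default rounding is
often half-to-even, which would shift the count table for, e.g.,
$n_{obs}=4, s=0.5$.

Numerical/ordering conventions worth recording:

- Observations are expanded from the count table in a canonical cell order,
  then the *order* is shuffled before noise is applied. MI is
  order-invariant, so this convention cannot affect any statistic; it is a
  documented choice, not an inference.
- Noise permutes the selected $Y$ values with a uniform random permutation,
  which may fix some values — no derangement is forced. Marginals are
  preserved exactly because the $Y$ multiset is untouched.
- $n_{obs}$ not divisible by 4 is rejected by default; with
  `allow_any_nobs = TRUE` the remainder over the uniform base table is
  placed deterministically (diagonal cells first), keeping marginals as
  balanced as the count allows.
- All randomness flows through explicit per-call seeds; ensemble and sweep
  functions derive independent child seeds from one master seed, so results
  are exactly reproducible and the caller's RNG state is never disturbed.

**What the model does and does not emulate.** It reproduces the essential
obstacles of real ensemble analyses — finite-sample MI bias, per-source
surrogate testing, ensembles of exchangeable sources — under fully known
conditions. It does *not* emulate temporal structure, heterogeneous sources
(mixtures of different $s$ within one ensemble), more than two states,
continuous variables, or dependence *between* sources (all sources are
independent). Passing calibration tests on this model therefore
demonstrates the statistical machinery is sound, not that any particular
real data set satisfies its assumptions — in particular real functional
connections sharing a neuron are not independent.

# Per-source statistics

MI is computed by the plug-in estimator in bits
($\hat p(x,y) = $ counts$/n_{obs}$, $I = \sum \hat p \log_2 (\hat p /
\hat p_x \hat p_y)$, with $0\log 0 \equiv 0$). No bias correction is
applied: bias is handled by the surrogate null, which shares the sample
size and marginals and is therefore equally biased.

Surrogates permute all $Y$ states uniformly; the Monte Carlo p-value is the
fraction of the $n_{MC}$ surrogate values **greater than or equal to** the
observed value (ties count toward the null), floored at $1/(2 n_{MC})$ when
no surrogate reaches it. The observed value is *not* added to the null set
— the common $+1$ convention is deliberately not used, so the floor, not
$1/(n_{MC}+1)$, is the smallest attainable value. Consequently p-values
live on a discrete grid in $[1/(2n_{MC}), 1]$ and are mildly conservative
under the null (their mean exceeds 0.5 because of ties at discrete MI
values).

# Ensemble statistics

**Ensemble versus null.** The $n_{ens}$ observed values are compared with
all $n_{ens} \cdot n_{MC}$ pooled surrogate values by a two-sample,
two-sided KS test. Two-sidedness matters: an ensemble whose values are
skewed *below* its null (e.g., a nearly deterministic low-$s$, low-$a$
system that is less variable than its fully permuted surrogate) is detected
just as an information-rich ensemble is. Because only the pooled null
enters, as few as ~10 surrogates per source suffice for this test even
though per-source p-values would be far too coarse. The asymptotic KS
p-value is used by default (`exact = FALSE`); sample sizes here are
$n_{ens}$ against $n_{ens} n_{MC}$, and discrete MI values produce massive
ties, under which exact small-sample computations are unavailable anyway.

A consequence worth stating plainly: with heavily tied discrete data the
asymptotic KS p-value is **conservative**. On fully null model ensembles
($n_{ens}=40$, $n_{obs}=60$, $n_{MC}=100$) the measured rejection rate at
$\alpha = 0.05$ is about 0.005, not 0.05. The test never over-rejects in
our measurements, but a user should know that its nominal level is an upper
bound in this discrete regime; the coarser the attainable MI grid (small
$n_{obs}$), the stronger the effect.

**Weighted summaries.** Weights are $w_i = -\log_{10} p_i$, normalized to
sum to 1. Sources at the p-value floor dominate; sources with $p_i = 1$
get zero weight. If *every* source has $p_i = 1$ the weights degenerate to
all-zero; the package falls back to uniform weights with a warning so fully
null ensembles remain summarizable. The summaries are:

- weighted mean $\bar I = \sum_i w_i I_i$;
- weighted SEM $\sigma_{\bar I} = \sqrt{\tfrac{1}{n_{ens}-1}\sum_i (I_i -
  \bar I_u)^2 \cdot \sum_i w_i^2}$ with $\bar I_u$ the unweighted mean —
  the unweighted sample SD scaled by $\sqrt{\sum w_i^2}$, which reduces to
  the classical SEM under uniform weights ($\sum w_i^2 = 1/n$). This is a
  design decision: of the candidate readings of a weighted SEM with
  normalized weights, it is the only one that is dimensionally consistent
  and recovers the classical formula in the uniform limit;
- weighted SD, default convention `"weighted-deviation"`
  $\sqrt{\sum_i (w_i (I_i - \bar I))^2}$, with the conventional
  `"weighted-variance"` form $\sqrt{\sum_i w_i (I_i - \bar I)^2}$
  selectable. The two differ (0.354 vs 0.5 for values $(0,1)$ with equal
  weights) and both are tested; results report which convention was used.

No family-wise error correction is applied to per-source p-values or
weights — the ensemble-level tests, not the individual sources, carry the
inferential claims.

**Comparing two ensembles.** The observed statistic is
$\Delta = \bar I_A - \bar I_B$. The permutation null pools all
(value, raw weight) pairs, deals them back into groups of the original
sizes, **re-normalizes the weights within each permuted group** (without
this the permuted group weights would not sum to 1 and the weighted mean
would be ill-defined), and recomputes the difference. The default p-value
is one-sided in the observed direction — the proportion of permuted
differences at least as extreme as $\Delta$ on $\Delta$'s side, ties
counting as extreme, floored at $1/(2 n_{perm})$; when $\Delta = 0$ every
permutation qualifies and $p = 1$. Because the direction is chosen after
seeing the data, this directional p-value roughly doubles the type-I rate
if used as a fixed-level two-group test (measured ~0.12 at nominal 0.05 on
matched ensembles); `alternative = "two.sided"` (comparing $|\Delta^*|$
with $|\Delta|$) is the calibrated choice (measured ~0.06 at nominal 0.05)
and is what the package's own calibration tests use. The directional value
is retained as the default because it answers the reported quantity — the
probability of so large a difference *in the observed direction* — and
matches how the comparison is conventionally quoted.

# Experiments and problem sizes

`run_noise_demo()` builds matched ensembles at noise levels
$a \in \{0.1, 0.5, 1.0\}$ (a package choice spanning low, medium, and
fully noisy regimes; the levels are configurable), summarizes each against
its null and compares all pairs. `run_significance_sweep()`,
`run_low_information_sweep()`, and `run_comparison_sweep()` scan parameter
grids and return tidy one-row-per-evaluation data frames; every sweep is
byte-reproducible from its master seed.

The packaged tests exercise these at deliberately moderate scales — e.g.,
calibration over 500 null sources and 200 null ensembles at
$(n_{ens}=40, n_{obs}=60, n_{MC}=100)$, noise-monotonicity over 100 seeded
runs, an 8-point signal grid with 20 replicates, and a $3\times 3$
comparison grid with 10 replicate pairs plus 400 matched seed pairs for
type-I measurement. These sizes were chosen as the smallest at which the
binomial noise of a measured rate is well inside the asserted bands;
larger grids are a matter of passing larger arguments.

The below-null ("suppressed information") regime deserves a note: its
detectability depends strongly on $n_{ens}$, $n_{obs}$, and $n_{MC}$. At
the moderate scales above, only the degenerate $s=0, a=0$ ensemble (MI
identically zero) is reliably declared significantly below null; shallow
suppression at small positive $s$ and $a \in \{0.2, 0.3\}$ needs larger
ensembles than these defaults to clear a 0.01 threshold. The sweep exposes
all three sizes as explicit configuration rather than fixing them.

# Known limitations

- **Homogeneity.** The ensemble-versus-null KS test pools surrogate values
  across sources; it presumes sources generated under a common regime.
  Heterogeneous ensembles (mixed $s$, mixed $n_{obs}$) are not modeled or
  tested here.
- **Conservative KS under ties** (discussed above): nominal levels are
  upper bounds for discrete data.
- **Directional comparison p-values** are not calibrated fixed-level
  tests; use `two.sided` when a rejection decision at a stated level is
  the goal.
- **Plug-in MI only.** Other information measures enter only via
  externally computed values + nulls through `info_ensemble()` /
  `read_ensemble()`; the package does not estimate transfer entropy,
  synergy, or continuous-variable information itself.
- The binary-pair model's MI takes ~$n_{obs}/2$ attainable values; very
  small $n_{obs}$ makes every distribution in the pipeline coarse, which
  is faithfully reflected in (not hidden by) the statistics.
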