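---
title: "Multi-epoch skyline inference from a site frequency spectrum"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-epoch skyline inference from a site frequency spectrum}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stairsfs)
```

## The model

A sample of $n$ haploid sequences coalesces through $n-1$ intervals: while
$k$ ancestral lineages remain, the population has effective size $N_k$ and
scaled mutation rate $\theta_k = 4 N_k \mu$, with $\mu$ the per-site
per-generation mutation rate.  Holding size constant *within* each
coalescent interval but letting it change *between* intervals gives a
flexible multi-epoch ("skyline") model that can approximate any
single-population history with up to $n-1$ steps.

Under this model the expected per-site count of sites whose derived allele
is carried by $i$ of the $n$ sequences is

$$E[\xi_i] \;=\; \sum_{k=2}^{n} \frac{\theta_k}{k-1}
  \frac{\binom{n-i-1}{k-2}}{\binom{n-1}{k-1}},
  \qquad i = 1, \dots, n-1,$$

which reduces to the classical $\theta/i$ when all $\theta_k$ are equal
(`expected_sfs()` and the test suite verify this identity, exactly in
rational arithmetic for $n \le 50$).  When ancestral alleles are unknown
the spectrum is folded — classes $i$ and $n-i$ collapse onto the
minor-allele class — and the expectations fold the same way, so polarized
data are not required.

The data are a single observed SFS $\eta_0, \eta_1, \dots$ over
$l_n$ sites (monomorphic sites included).  Sites are treated as independent,
giving the composite (multinomial) likelihood

$$L_n \;=\; l_n!\prod_i \frac{p_i^{\eta_i}}{\eta_i!},$$

where $p_i$ is the model probability of class $i$: $p_i = E[\text{class}_i]$
for polymorphic classes and the monomorphic class absorbs the remainder,
$p_0 = 1 - \sum_{i\ge1} p_i$.  The likelihood is a genuine function of
$\theta$ only under this reading, which is why the package adopts it.  With
a mask (e.g. dropping singletons, whose calls are least reliable) the
probabilities are renormalized over the unmasked classes and the masked
counts leave both the product and $l_n$.

## Overfitting control

A model with $n-1$ free $\theta$s will happily fit noise.  Two constraints
keep it honest:

1. **Site subsampling.**  Each replicate draws $2/3$ of the $l_n$ sites
   without replacement (a multivariate hypergeometric draw over classes) as
   a training spectrum; the held-out third is the testing spectrum.
   Subsampling, unlike bootstrapping, leaves a genuinely disjoint test set.
2. **Breakpoint constraint.**  Consecutive $\theta$s are grouped; a
   "breakpoint" between positions allows the groups on either side to
   differ, so $m$ breakpoints give $m+1$ free parameters.  For each
   replicate and each candidate count $m$, the $m$ allowed positions are
   drawn at random from the $n-2$ possibilities (in the spirit of random
   feature subsetting in random forests), and the fit may only use
   breakpoints from that subset.

Within a replicate the grouping is found by greedy forward selection:
starting from a single epoch, the candidate breakpoint that most improves
the training log-likelihood is added, and acceptance requires an
improvement greater than 1.92 — the $\chi^2_1$ half-deviance criterion for
one extra parameter at the 5% level, i.e. each breakpoint must pass a
likelihood-ratio test.  An epsilon-threshold greedy was evaluated and
rejected during development: with ~10 informative folded classes it
saturates the model on every replicate, driving alternating $\theta$ groups
to the numerical floor and making individual trajectories (and even their
ensemble median) collapse.  The LRT threshold is configurable
(`inference_config(greedy_threshold=)`).  The search also respects the
identifiability cap: distinct $\theta$ groups never exceed the number of
unmasked SFS classes, monomorphic included.

The mean test log-likelihood over the $B$ replicates, $G_m$, measures how
well complexity $m$ generalizes.  Scanning candidates in increasing order,
the method advances to a larger $m$ only when its $G_m$ beats every smaller
candidate's by more than 1.92; read literally, "the smallest $m$ satisfying
the rule" is vacuously the smallest candidate, so the stepwise-improvement
interpretation is used.  A consequence worth knowing: the selected $m$ can
sit up to 1.92 log-likelihood units below the best $G_m$ — a deliberate
preference for the simpler model.  Because the within-replicate search is
itself LRT-regularized, $G_m$ is typically weakly increasing in $m$ at desk
scale, and the selection mostly expresses this parsimony preference rather
than guarding against a collapse at large $m$.

## From thetas to a population-size history

Each replicate's fit converts to a step function: boundary times
$T_i = \sum_{k=i}^{n} \theta_k/(k(k-1))$ (expected mutations per site;
divide by $\mu$ for generations, multiply by generation time for years) and
size $N_k = \theta_k/(4\mu)$ on the $k$-lineage interval $(T_{k+1}, T_k]$.
The final estimate at each time point is the pointwise **median** of the
$B$ replicate step functions; 75% and 95% percentile bands (type-7
quantiles) summarize the ensemble spread.  The evaluation grid is 300
log-spaced points from the 2.5th percentile of the replicates' most recent
boundaries to the 97.5th percentile of their oldest ones — outside its own
span a replicate contributes its oldest size (the flat ancient tail seen in
skyline-style plots); both axes are naturally viewed on log scale.
Individual replicate fits are deliberately coarse (few epochs); the
smoothness of the final curve comes from the ensemble step.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `B` | 200 | subsample replicates (50 is plenty for exploratory runs) |
| `training_fraction` | 2/3 | share of sites in each training subsample |
| `candidate_m` | $\approx \frac14, \frac12, \frac34, 1 \times (n-2)$ | breakpoint counts compared by $G_m$ |
| `mu` | 1.2e-8 | mutation rate / site / generation |
| `year_per_generation` | 24 | generation time (1 = report generations) |
| `greedy_threshold` | 1.92 | LRT acceptance gain per breakpoint |
| `theta_floor` | 1e-12 | lower bound on any fitted $\theta$ (keeps logs finite) |
| `grid_points` | 300 | summary grid resolution |

All randomness derives from one master seed: replicate $b$ receives a
pre-assigned child seed, so results are independent of execution order and
a run is reproducible bit-for-bit from its manifest.

## The synthetic-data generators

`simulate_coalescent_sfs()` draws genealogies under any piecewise-constant
or exponential-growth single-population model (ms-style scaling: times in
$4N_0$ generations, sizes relative to $N_0$; exponential segments are
handled by exact integrated-hazard inversion) and drops Poisson mutations
on branches by descendant count.  `model_presets()` ships the zig-zag,
sharpCEU and sharpYRI histories decoded from their published simulator
command lines, plus a flat control.  Two deliberate departures from
chromosome-scale simulators: there is **no recombination** (sites are
spread over `blocks = 1000` independent genealogies instead — the composite
likelihood ignores linkage anyway, and 1000 blocks is a desk-scale choice,
so simulated spectra are noisier between classes than recombining 10-Mb
chromosomes would be), and the infinite-sites model is assumed (no multiple
hits).  `simulate_skyline_sfs()` instead draws one multinomial from the
inference model's own class probabilities — the exact generating process
the likelihood assumes — which makes parameter-recovery tests clean of any
simulator/model mismatch.  Passing tests on these generators therefore
demonstrate correctness of the machinery and statistical behaviour under
the model's assumptions, not robustness to linkage, ascertainment or
mispolarization in real data.

`oracle_expected_sfs()` is a brute-force Monte-Carlo check of the
closed-form expected SFS, used only in validation.

## Numerical choices

Binomial coefficients are evaluated through `lchoose()` so the design
matrix is stable for $n$ in the thousands.  Per-grouping optimization runs
L-BFGS-B on $\log\theta$ per group with an analytic gradient, initialized
from a Watterson-style moment estimate (polymorphic fraction over the
harmonic number), bounded below by `theta_floor`, with relative convergence
tolerance $\approx 10^{-9}$; the constraint that per-site polymorphic
probability stay below 1 is enforced by a steep linear penalty, far from
any realistic optimum.  Greedy ties are broken by the smallest breakpoint
position; warm starts carry group values into each refined grouping.
Degenerate inputs behave predictably: an all-monomorphic training spectrum
pins every $\theta$ at the floor; an observed class with zero model
probability yields a $-\infty$ log-likelihood sentinel rather than an
error; a replicate whose fit fails is retried with a fresh child seed at
most three times.

## Problem sizes used in validation

The test suite exercises full inferences at $n = 20$ haploids over $10^7$
sites with $B = 50$ replicates (and 20 repeated simulations at $B = 10$ for
the model-selection study) — sizes chosen so the whole suite runs in a few
minutes on one core while the statistical properties (constant-size
recovery within a few percent, two-epoch recovery within 25%, folded vs
unfolded agreement within 2-fold) remain sharp.  At this scale a folded
spectrum carries only 10 informative classes, so sharply oscillating
histories are recovered only coarsely; resolution improves with $n$, and
the operating point of the published analyses ($n = 200$, $B = 200$,
hundreds of megabases) is reached by changing nothing but the inputs.

## Known limitations

Single panmictic population only — no migration, admixture or population
structure; no linkage modelling (composite likelihood); no smoothing of the
median beyond ensemble aggregation; confidence bands reflect subsampling
variation, not model misspecification.  The blueprint dialect is
deliberately minimal and is not bit-compatible with any other tool's.
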