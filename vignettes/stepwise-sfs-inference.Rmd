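---
title: "Stepwise demographic inference from the site-frequency spectrum"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stepwise demographic inference from the site-frequency spectrum}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sfstep)
```

## The model and its assumptions

The observed object is a site-frequency spectrum: among `n` haploid
genomes surveyed at `L` nucleotide sites, `G_r` sites carry `r` copies
of the derived allele (`r = 1..n-1`), or — when ancestral states are
unknown — `F_r = G_r + G_{n-r}` sites carry a minor allele in `r`
copies. The method assumes the sites are effectively neutral, have
evolved without strong population structure, and follow the
infinite-sites mutation model (each mutation hits a new site), with a
known mutation rate `u` per site per generation.

Genealogically, the sample coalesces through levels `k = n, ..., 2`,
where level `k` is the epoch with exactly `k` ancestral lineages. The
central modelling idea is to give every level its own diploid effective
size `N_k`, so the expected level duration is `t_k = 4 N_k / (k(k-1))`
generations. Population size is therefore piecewise-constant *on the
genealogy's own clock*: changes are aligned with expected coalescence
events rather than with calendar times. This granularity is the price
of a model-flexible fit; with growing `n` the level grid refines, and
the fitted step function can approximate continuous size changes.

The probability structure of where a class-`r` mutation can sit in the
tree is independent of the demography; only branch lengths depend on
the `N_k`. That yields a closed-form expected spectrum,

E[G_r] = (4uL/r) · Σ_{k=2}^{n−r+1} [C(n−k, r−1)/C(n−1, r)] · N_k,

a weighted average of the level sizes whose weights sum to one (the
hockey-stick identity). Two limits anchor it: constant `N` gives the
classical `4NuL/r`, and the singleton class always measures the
arithmetic mean of `N_2..N_n`. The package also carries an independent
second route to the same expectations (`expected_sfs_via_W()`), built
from the expected number of order-`r` branch segments present at each
level, `W_k(r) = k·C(n−r−1, k−2)/C(n−1, k−1)`, of which a fraction
`(r−1)/(n−k)` start there, combined with the mean mutation probability
`4u·mean(N_2..N_k)/k` of a branch starting at level `k`. The two routes
agree to ~1e−15 relative in the tests; the weighted-average form is the
one used everywhere else, and would be authoritative if the routes ever
disagreed.

## Likelihood and optimisation

Class counts are treated as independent Poisson variables with means
equal to the expected spectrum — a composite likelihood, since linked
sites share genealogies. The log-likelihood (constants dropped) is
`Σ_r G_r log μ_r − μ_r` over non-excluded polymorphic classes. Two
deliberate choices:

* **The monomorphic class is excluded by default.** The polymorphic
  Poisson terms carry all the information about the `N_k`, and omitting
  `G_0` keeps the means independent of the (enormous, uninformative)
  monomorphic count. A switch (`include_monomorphic = TRUE`) adds the
  `G_0` term with mean `L − Σ μ_r` for sensitivity checks; for
  realistic `u L` the two versions are numerically indistinguishable.
* **Classes can be excluded** (e.g. singletons inflated by sequencing
  error); excluded classes stay in the data object so folding and
  bootstrapping remain exact, and are skipped only inside likelihood
  sums.

With `n − 1` free sizes and at most `n − 1` (often fewer, for folded
data) observed classes, the per-level model is over-parameterised, so
levels are pooled: a *breakpoint* at level `b` lets `N_i` take one
value for `i > b` and another for `i ≤ b`. Every expected count is
*linear* in the group sizes, so the composite likelihood is concave on
the positive orthant and the fixed-breakpoint problem has a unique
maximum. It is found by a damped Newton iteration on the log sizes
(positivity for free), with analytic gradient and Hessian, an Armijo
step-halving line search, and a steepest-ascent fallback if the
(log-scale) Hessian loses definiteness at a far-from-optimum point.
Convergence requires a projected-gradient norm below
`1e−8 · max(1, |logL|)` within 200 iterations; anything else is
reported as non-converged, never silently returned. Sizes are floored
at `1e−6` times the Watterson estimate, and log-sizes are capped at 170
so no intermediate overflows. All starting values are the Watterson
estimate `S/(4uLa)`, `a = Σ_{i<n} 1/i`, which is exactly the
zero-breakpoint maximum-likelihood solution.

The stepwise search starts from that constant model and adds one
breakpoint per iteration. *Greedy* mode keeps accepted breakpoints and
tries each unused level (re-optimising all sizes jointly); *exhaustive*
mode re-evaluates every size-`m` subset of candidate levels at step
`m`, so earlier breakpoints can move; its cost grows combinatorially,
hence a default cap of 3 breakpoints (greedy defaults to `n − 2`). A
proposal is accepted only if it gains at least 2.0 log-likelihood units
— the conventional information-criterion cost of one extra parameter,
exposed as `threshold`. Equal-likelihood ties go to the smallest
(most root-ward) level, making the search fully deterministic. Folded
spectra use folded means throughout (`E[F_r]`), with the same candidate
levels; the likelihood-gain stop handles their weaker identifiability.

Breakpoints are converted to times through the fitted expected interval
lengths, giving the `(start time, Ne)` step plot. Times are reported in
generations; any generations-per-year conversion is left to the user.

## Allele ages and experienced population size

For each class the same interval algebra gives closed-form moments of
the allele's age `A_r` (mean and second moment, hence variance) and the
mean size experienced over its lifetime,
`E[P_r] = E[∫₀^{A_r} N(s) ds] / E[A_r]` — a *ratio of expectations*,
not an expectation of ratios. `E[P_r]` is a weighted average of the
`N_k`, so it always lies within their range and equals `N` exactly
under constant size. Folded classes are mixtures of derived order-`r`
and ancestral order-`(n−r)` alleles with weights
`pd = E[G_r]/(E[G_r]+E[G_{n−r}])` and `pa = 1 − pd`; folded age means,
age variances (`pd²·Var + pa²·Var` form) and experienced sizes use
these weights. A variance for the folded experienced size is not
defined here and is not reported. Inner sums over levels are suffix
cumulative arrays (O(n) per class) and all binomial coefficients are
evaluated via `lchoose` with a common normalisation subtracted before
exponentiation, so samples of several hundred genomes are safe.

## The simulator: what it emulates, what it does not

The package's coalescent simulator is both the synthetic-data source
and the Monte-Carlo oracle. It draws level waiting times (exponential
with mean `4N_k/(k(k−1))` in level-indexed mode; rate
`k(k−1)/(4N(t))` integrated across epochs in time-indexed mode), merges
uniformly chosen pairs, and places Poisson mutation counts on branches
— the exact infinite-sites shortcut, O(branches) instead of O(L).
Mutations are positioned uniformly along their branch; this is what
makes the pairwise-sample closed form (mean singleton age `2N`, second
moment `8N²`) hold, and the tests verify exactly that. For mutation-age
records, the lifetime integral `∫N(s)ds` uses the genealogy's own
realised level intervals in level-indexed mode — the correct oracle for
the ratio-of-expectations definition — and the fixed epochs in
time-indexed mode. Because mutations sharing a genealogy are
correlated, Monte-Carlo standard errors treat genealogies, not
mutations, as the independent units (cluster-robust ratio-estimator
variances).

`simulate_sfs()` splits `L` sites across a chosen number of unlinked
loci. Real genomes deliver an *effective* number of independent
genealogies set by recombination; the generator's locus count stands in
for that. The validation experiments use 1,000–2,000 loci for 1e6–1e7
sites, i.e. the many-independent-genealogies regime in which the
composite likelihood and the site-wise multinomial bootstrap are
well calibrated. With few loci the SFS classes become strongly
correlated, point estimates wander, and the bootstrap band (which
resamples sites, not genealogies) understates the true variance — passing
tests therefore demonstrate correctness in the weak-linkage regime, not
robustness to pervasive linkage. No recombination, selection, or
population structure is simulated.

The bootstrap resamples the `L` sites multinomially over classes
`0..n−1` (monomorphic included), conserving `L` exactly; this is the
only resampling scheme expressible from the SFS alone. Replicate fits
are evaluated on a common logarithmic time grid (default 200 points
between the 1st and 99th percentile of replicate step times) for
pointwise means, medians and quantiles; `aggregate_histories()` applies
the same grid convention (right-continuous steps, flat tails) to
average histories from independent spectra, unweighted by default with
an optional weights argument.

## Numerical choices and degenerate inputs

* θ scaling is diploid (`θ = 4N_k u`) throughout; for haploid data,
  supply `2u` in place of `u` (equivalently, sizes are reported in
  units of `θ/(4u)`).
* Zero counts are legal everywhere (`G_r log μ_r` term dropped,
  `−μ_r` kept); an SFS with `S = 0` fits to the size floor.
* A class with zero expected count but positive observed count returns
  `−Inf` likelihood and is flagged rather than crashing.
* Expected spectra accept real-valued "counts" so that exact noiseless
  inversion can be tested; observed spectra are integers.
* Determinism: every stochastic entry point takes a seed, and fixed
  seeds give bit-identical results.

## Problem sizes used in validation

The shipped experiments are sized to run comfortably on one CPU:
closed-form identities are swept over `n` up to 200–300; simulator
agreement uses 1e5 genealogies per scenario for `n ∈ {2, 4, 8, 20}`;
mutation-age oracles use 2–3e4 genealogies; the two-epoch recovery
experiment uses `n = 20`, `uL = 0.1` (1e7 sites at `u = 1e−8`), 2,000
loci and 200 bootstrap replicates, mirroring — at reduced replicate
count — the published practice of 2,000–10,000 bootstraps.

## Known limitations

Inference degrades at very ancient times (few surviving polymorphisms
older than ~`4Ne` generations; the most root-ward levels are informed
by few classes) and at very recent times (no power over spans in which
no sampled mutation is expected to arise). The likelihood-gain stop is
a forward selection on a composite likelihood: with many candidate
levels it retains some liberality, which the bootstrap bands — not the
point estimate alone — are meant to absorb. The method estimates
`N_k` only up to the scale fixed by `u` (`u·N` identifiability), so an
inaccurate mutation rate rescales the whole history, sizes and times
alike.
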