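---
title: "Models and methods behind sgsd"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind sgsd}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`sgsd` implements the analysis chain of fine-scale population-genetic
studies on georeferenced codominant genotypes: quality control, genetic
clustering, diversity and differentiation statistics, spatial genetic
structure (SGS), indirect gene-dispersal estimation, and selfing-rate
estimation. This vignette states each model precisely, explains the
tunable parameters and the numerical choices, and is explicit about what
the bundled simulators do and do not establish.

## Data model

A `genotype_table` holds diploid genotypes (allele states = positive
integers; for microsatellites, repeat units or fragment sizes in bp), one
pair per locus, either fully typed or fully missing. Coordinates are
planar meters or geographic decimal degrees (x = longitude); all reported
distances are meters (great-circle on a 6,371,000 m sphere for geographic
input), because typical datasets mix sub-100 m neighbourhoods with
hundreds of km between clusters. Allele pairs are unordered and stored
sorted. On input, `0` (the common convention) and empty cells mean
missing.

## Quality control

* `filter_min_typed_loci()` keeps samples typed at ≥ 60% of loci by
  default (six of ten loci for a standard 10-SSR panel).
* `detect_duplicates()` flags pairs identical at every locus typed in
  both, provided ≥ 5 loci overlap. Because published studies rarely state
  the exact relationship estimator/cutoff they used for clone detection,
  the rule here is exact-match-with-overlap-floor, and the mean
  proportion of shared alleles per locus is reported so users can apply
  their own threshold.
* `grid_subsample()` thins over-represented areas to at most 3 samples
  per 0.01° × 0.01° cell (≈ 1 km² near the equator), with the grid
  anchored at (0°, 0°) for reproducibility and ties broken by a seeded
  uniform draw.

## Diversity statistics

Per locus with `n` observed gene copies and allele frequencies `p_a`:

* unbiased expected heterozygosity `He = n/(n−1) · (1 − Σ p_a²)`;
* observed heterozygosity `Ho` = fraction of typed genotypes with two
  distinct alleles;
* effective allele number `NAe = 1 / Σ p_a²`;
* rarefied allelic richness
  `AR(k) = Σ_a [1 − C(n − n_a, k)/C(n, k)]` (binomials in log space), the
  expected number of distinct alleles among `k` copies drawn without
  replacement. `k` must not exceed any locus's copy count; the default is
  the largest valid `k` per group.

Multilocus values are unweighted means over loci — matching how such
studies report a single value per cluster — except the inbreeding
coefficient, which pools variance components.

## Variance-component engine (Fi, FST, RST)

One method-of-moments nested ANOVA on gene-copy values (copies within
individuals within groups) underlies three statistics. For a value `y`
attached to each gene copy it yields components `a` (among groups), `b`
(among individuals within groups), `c` (within individuals):

* **Fi** (within-group inbreeding): `y` = allele indicators, single
  group, `Fi = Σb / (Σb + Σc)` summed over alleles and loci. This equals
  the Weir & Cockerham within-population f exactly. Significance comes
  from permuting gene copies among individuals within the group,
  re-pairing copies at each locus independently (a Hardy–Weinberg null);
  p-values use the (r+1)/(n+1) correction, two-sided by doubling the
  smaller tail (the one-sided upper p is also reported, since published
  tables usually do not say which was used).
* **FST**: `y` = allele indicators, two groups per pair;
  `θ = Σa / Σ(a+b+c)` summed over alleles and loci — the Weir & Cockerham
  (1984) estimator (the package's vectorized route and the printed 1984
  formulas agree to machine precision; the test suite asserts this).
  Negative estimates are reported as computed.
* **RST**: the same ANOVA with `y` = allele size. Components are summed
  over loci before the ratio (ratio of sums, not mean of ratios), which
  is stable for low-polymorphism loci. With two alleles one repeat unit
  apart at every locus, sizes are an affine transform of indicators and
  RST = FST identically — a property the tests assert.

**Allele-size permutation test.** Sizes are shuffled among the distinct
allele states within each locus (genotype identities kept) and RST is
recomputed; the one-sided p is the proportion of permuted RST ≥ observed.
The permutation null is "sizes carry no information beyond identity",
i.e. an FST-like statistic; a significant result means stepwise mutations
contribute to differentiation (RST > FST). Default 10,000 permutations.

## Loiselle kinship and the Sp statistic

For individuals i, j and reference frequencies `p_a` estimated from `n_l`
copies:

```
num_ij = Σ_loci Σ_a [ (x_ia − p_a)(x_ja − p_a) + p_a(1−p_a)/(n_l − 1) ]
den_ij = Σ_loci Σ_a p_a(1−p_a)          (loci typed in both only)
Fij    = num_ij / den_ij
```

with `x_ia ∈ {0, ½, 1}`. The bias term makes the average over pairs of
the reference sample ≈ 0; parent–offspring pairs sit near 0.25. Per-locus
numerators/denominators are retained so delete-one-locus jackknives are
exact.

`kinship_distance_analysis()` reports the kinship–distance curve over
log-spaced distance classes (first bound 100 m — the conventional
neighbour scale), the OLS slope `b` of pairwise Fij on ln(d) over pairs
(class means are for plotting only; regressing on pairs is the standard
definition), `F1` (mean kinship in the first class), `Fn` (mean kinship
below 100 m; zero-distance pairs count here but are excluded from the log
regression), and `Sp = −b/(1 − F1)`. Significance: locations are permuted
among individuals and the slope recomputed (default 10,000 permutations,
two-sided rank p). The jackknife SE of Sp deletes one locus at a time.
Whether published analyses restricted the regression range is usually
unstated; all pairs is the default and a `range` argument covers the
restricted variant.

## Indirect gene dispersal (iterative Wright–Malécot)

Under two-dimensional isolation by distance, kinship decays approximately
linearly in ln(distance) at rate `(Fn − 1)/(4π·De·σg²)` for distances
between `σg` and about `0.56·σg/√(2µ)`. With `De` fixed by the user
(never inferred from sample coordinates — sampling intensity is not
census density), the estimator iterates:

1. regress Fij on ln(d) over pairs with `σg < d ≤ min(20·σg, max_distance)`
   (`range_factor` 20 or 100);
2. `Nb = (1 − Fn)/(−b)`, requiring `b < 0`;
3. `σg ← sqrt(Nb / (4π·De))`;

until the relative change is below `tol`. Reported `Nb` always equals
`4π·De·σg²` at the returned `σg`. Design choices that matter:

* **Initialization** is from the slope over the full (capped) range; when
  that overshoots, the start value is clamped to `max_distance/4` so the
  first window spans at least a factor 4 and the fixed point is
  approached from below.
* **Damping and cycles.** The window → slope map is piecewise constant in
  `σg`, so the raw update can oscillate between two windows forever at
  any tolerance. The update is therefore the geometric mean of the old
  and proposed values, and revisiting an earlier value within `tol` ends
  the iteration at the cycle mean (flagged). `tol = 1e-3` by default;
  1e-2 is plenty given estimator noise.
* **`max_distance`** (default `Inf`, giving the plain procedure): because
  Loiselle kinship is centered on the sample, the kinship curve must
  cross zero within the sampled extent and is forced flat near the
  maximum observable distance. On a bounded or periodic sampling area
  (e.g. the bundled torus simulator, or a single forest plot), windows
  reaching that scale bias the slope toward zero and push the iteration
  upward; capping at about half the extent removes the artefact.
* **Non-convergence** (window starved of pairs, `b ≥ 0`, max iterations)
  is an expected outcome on data without usable isolation-by-distance
  signal — real studies report exactly this for some clusters — and is
  returned as `converged = FALSE` with flags, never as an error.
* With a user-supplied `µ`, a warning fires when the window exceeds the
  theoretical validity bound `0.56·σg/√(2µ)`.

`density_scenarios()` converts a census density (per ha) into the
conventional De guesses (½, ¼, 1/10 of D) in per-ha and per-m² units.
Across such scenarios `Nb` is nearly invariant while `σg` scales as
`De^{-1/2}` — the acceptance suite checks both.

## Selfing from identity disequilibrium

With heterozygosity indicators `h_il`, each locus pair (k, l) contributes
over the individuals typed at both: numerator `Σ_i h_ik·h_il / n_kl` and
the unbiased independence baseline
`Σ_{i≠j} h_ik·h_jl / (n_kl(n_kl − 1))`; pairs are weighted by `n_kl` and
`ĝ2 = Σnum/Σbase − 1`. Cross-individual products (rather than a plug-in
product of means) remove the finite-sample bias, verified against a
Hardy–Weinberg null simulation; loci without variation in `h` are
excluded (they carry no information). Under mixed mating at equilibrium
the number of consecutive selfed ancestor generations is geometric and
heterozygosity halves per selfed generation, giving

```
g2(s) = (1 − s/2)² / ((1 − s)(1 − s/4)) − 1
```

which the package inverts by bracketed root finding (`ĝ2 ≤ 0 → s = 0`;
values beyond the s → 1 asymptote saturate at 1 − ε with a flag). This
relation was verified against a Monte-Carlo simulation of the geometric
process before being relied on (the check lives in the test suite,
Rao-Blackwellized over the per-locus Bernoulli layer because plain
Bernoulli draws at 10⁶ samples are too noisy for a 3-decimal
comparison). Because g2 depends on genotypes only through heterozygosity
ratios, converting random heterozygotes to apparent homozygotes (what
null alleles do) cancels in the ratio — the motivation for this
estimator. SEs are delete-one-locus jackknives; estimates are labelled
significant when 0 lies outside ±1.96·SE.

## EM genetic clustering

A K-component mixture in which each cluster is a Hardy–Weinberg
population with its own allele frequencies and no admixture:
`P(g_i | k) = Π_loci p_ka² or 2·p_ka·p_kb`. Missing loci drop out of the
product (missing at random). The M-step uses q-weighted allele counts
with a pseudo-count of `1/(2·n_l)` to keep frequencies positive; mixing
proportions are estimated (they appear in the AIC parameter count
`K·Σ(A_l − 1) + (K − 1)`), with uniform initialization via Dirichlet
fractional memberships. The best of 20 seeded restarts is kept; runs that
empty a cluster are restarted. `select_k()` minimizes AIC over K = 1..10
(ties toward smaller K), and `apply_admixture_threshold()` removes
individuals whose maximum membership is below 0.8 before per-cluster
statistics, mirroring standard practice. The log-likelihood trace is
retained and asserted non-decreasing. This model class deliberately
excludes MCMC admixture inference and null-allele modelling.

## Simulators: what they emulate, what they do not

`simulate_ibd()` is a forward-in-time, non-overlapping-generations model
on a torus: `N = D·L²` individuals at uniform positions; each offspring
draws a mother uniformly, selfs with probability `s`, otherwise draws a
father in proportion to a Gaussian kernel of SD `σp` in toroidal distance
(exact kernel via rejection sampling; a Gumbel-max weighted draw handles
kernels too narrow for rejection); the offspring settles at the mother's
position plus Gaussian `σs` noise; transmitted alleles mutate ±1 repeat
with probability `µ`, reflecting at the allele-range bounds (the strict
stepwise model that underlies RST). The composite truth is
`σg = sqrt(σs² + σp²/2)` (pollen moves only the paternal gamete), and the
simulator tracks realized parent–offspring gene displacement over the
last 10 generations as an internal consistency check (within 5% at
N ≥ 2000). Defaults — 500 generations of burn-in, µ = 10⁻³, 10 loci, 50
allele states — reach quasi-stationary SGS at desk scale.

The torus removes edge effects that would bias Wright–Malécot
regressions, but it also caps observable distances at `L/√2` and forces
the kinship curve flat at large distances; dispersal analyses of torus
data should cap the regression window (see above). The model does not
emulate: overlapping generations, demographic change, spatially clustered
habitat, genotyping error, or null alleles (the selfing estimator's
robustness to the latter is tested by explicit censoring instead). A
green recovery test therefore establishes estimator correctness under the
stated model, not robustness to all field realities.

`simulate_demes()` draws ancestral frequencies symmetric-Dirichlet per
locus and deme frequencies from the Balding–Nichols construction with
parameter `F` (the target FST), then samples genotypes in Hardy–Weinberg
proportions — the validation harness for FST/RST calibration, the
permutation tests' type-I error, and clustering recovery.
`inject_missingness()` deletes genotypes independently at a given rate to
check that every estimator tolerates real-data missingness.

## Numerical and reporting choices

* Permutation p-values always use (r+1)/(n_perm+1); default 10,000
  permutations (tests and examples scale this down for speed — stated
  wherever they do).
* All randomized functions take a seed and leave the global RNG state
  untouched (`withr::with_seed`); the pipeline derives per-stage seeds
  from one global seed.
* Degenerate inputs: pairs sharing no typed locus get `NA` kinship;
  group pairs with no usable locus get `NA` differentiation (flagged,
  never silently 0); a regression over pairs at one distance errors;
  dispersal non-convergence is a result, not an error.
* The pipeline config is JSON (round-trips losslessly); outputs are CSVs
  shaped like the field's standard report tables (diversity panel,
  FST-below/RST-above matrix, kinship–distance curves, one dispersal row
  per De scenario per group) plus a JSON manifest recording seeds and
  per-stage sample counts (`n_in = n_out + n_removed` is asserted in the
  tests).

## Known limitations

* FST/RST pairs are computed independently per pair; no hierarchical
  AMOVA beyond two levels, no bootstrap CIs over loci.
* The dispersal estimator assumes drift–dispersal equilibrium and a
  user-supplied De; on weak-signal data (neighbourhood sizes of several
  hundred with 10 loci and a few hundred samples) single-dataset
  estimates are noisy and non-convergence is common — averaging over
  replicate datasets, as the acceptance suite does, is then the honest
  summary.
* The clustering model ignores admixture LD and null alleles; admixed
  individuals are handled by exclusion (q threshold), not modelling.
* Geographic distances use a spherical earth (haversine), adequate at
  the accuracy of field GPS coordinates.
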