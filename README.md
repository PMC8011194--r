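# sgsd — spatial genetic structure and gene dispersal from microsatellite genotypes

`sgsd` is an R package for the population-genetic analysis chain used in
phylogeographic studies of plants and trees genotyped at codominant markers
(microsatellites/SSRs) with georeferenced samples. It is aimed at
researchers who have a table of diploid multilocus genotypes with
coordinates and want, from that single input:

* **sample-level QC** — minimum-typed-loci filtering, duplicate (clone)
  screening via shared-allele relationship coefficients, spatial grid
  subsampling of over-represented areas;
* **genetic clustering** — maximum-likelihood EM mixture model (each
  cluster a Hardy–Weinberg population), AIC selection of the number of
  clusters K, and a posterior-membership threshold (q ≥ 0.8 by default)
  separating assigned from admixed individuals;
* **per-cluster diversity** — expected/observed heterozygosity (He, Ho),
  effective number of alleles (NAe), rarefied allelic richness AR(k), and
  the inbreeding coefficient Fi with a gene-copy permutation test;
* **differentiation** — pairwise Weir–Cockerham FST and allele-size-based
  RST (variance components summed over loci before the ratio), plus the
  allele-size permutation test for a stepwise-mutation (phylogeographic)
  signal, i.e. whether RST significantly exceeds FST;
* **fine-scale spatial genetic structure (SGS)** — pairwise Loiselle
  kinship Fij, kinship–distance curves, the regression slope *b* of Fij on
  ln(distance), the statistic **Sp = −b / (1 − F1)**, a
  location-permutation test, and a jackknife-over-loci standard error;
* **indirect gene dispersal** — the iterative Wright–Malécot estimator:
  under isolation by distance, Fij decays with ln(distance) at rate
  (Fn − 1)/(4π·De·σg²), so with the effective density De fixed, the
  restricted-range regression slope yields the neighbourhood size
  **Nb = (1 − Fn)/(−b)** and the gene dispersal distance
  **σg = sqrt(Nb / (4π·De))** (σg² is half the mean squared
  parent–offspring distance);
* **selfing rate** — from identity disequilibrium g2 (correlation of
  heterozygosity across loci), inverting
  g2(s) = (1 − s/2)² / ((1 − s)(1 − s/4)) − 1, robust to null alleles,
  with jackknife-over-loci SEs.

Because the kind of dataset these studies use is rarely deposited, the
package bundles two first-class simulators used to validate every
estimator by parameter recovery: a forward-in-time, spatially explicit
torus model with Gaussian seed/pollen kernels, partial selfing, and
strictly stepwise (±1 repeat) mutation; and a Balding–Nichols deme
generator with a target differentiation F.

## Worked example

Simulate a population under isolation by distance (true σg =
sqrt(30² + 60²/2) ≈ 52 m at density 0.002 adults/m²), then recover the
spatial structure and the dispersal distance:

```r
library(sgsd)

p   <- ibd_params(side = 1000, density = 0.002, sigma_s = 30, sigma_p = 60,
                  loci = 10, mu = 1e-3, generations = 500, seed = 7)
sim <- simulate_ibd(p, sample_n = 300)
kin <- loiselle_kinship(sim$table)
dm  <- pairwise_distances(sim$table)

kinship_distance_analysis(kin, dm, n_perm = 999, seed = 1)
#> sgs_result: 44850 pairs; b_log = -0.00618, F1 = 0.0190, Fn(<100m) = 0.0190
#>   Sp = 0.00630 +/- 0.00072 (jackknife SE), permutation p = 0.002

estimate_sigma_g(kin, dm, De = 0.002, max_distance = 500, tol = 0.01)
#> dispersal_estimate: sigma_g = 55.5 m, Nb = 77.5 (De = 0.002 /m^2,
#>   range sigma_g..20sigma_g, 3 iterations)
```

The Sp statistic is positive and significant (kinship decays with
ln-distance), and the iterative estimator recovers σg ≈ 55 m against a
true value of 52 m. `max_distance` caps the regression window at half the
habitat extent — on a bounded (here periodic) sampling area the kinship
curve is forced flat near the maximum observable distance, which would
otherwise bias the slope toward zero.

Effective-density scenarios, as used when census density D is known but
the effectively reproducing fraction is not:

```r
density_scenarios(18)
#>   fraction De_per_ha De_per_m2
#> 1     0.50       9.0   0.00090
#> 2     0.25       4.5   0.00045
#> 3     0.10       1.8   0.00018
```

Selfing-rate estimation from identity disequilibrium (simulated
panmictic-scale population with a true selfing rate of 0.3):

```r
sim0 <- simulate_ibd(ibd_params(side = 1000, density = 2e-4, selfing = 0.3,
                                sigma_s = 240, sigma_p = 240, loci = 10,
                                mu = 1e-3, generations = 100, seed = 2))
selfing_with_jackknife(sim0$table)
#> mating_system_estimate [ALL]: g2 = 0.1452, s_hat = 0.347 +/- 0.023
#>   (10 loci, significantly > 0)
```

The full pipeline (QC → clustering → per-cluster diversity,
differentiation, SGS, dispersal, selfing, with CSV reports and a JSON
manifest) runs from a JSON config:

```r
cfg <- pipeline_config(input = "genotypes.csv", out_dir = "run",
                       density_per_ha = list(cluster1 = 18), seed = 1)
run_pipeline(cfg)
```

## Vignette

`vignettes/methods.Rmd` documents the statistical models, the estimators'
exact forms, the simulators' assumptions (and what they do not emulate),
numerical choices, and known limitations.
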