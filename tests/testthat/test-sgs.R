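test_that("Loiselle kinship matches brute-force enumeration to 1e-12", {
  tab4 <- random_table(n = 4, loci = 2, alleles = 3, miss = 0, seed = 91)
  kin <- loiselle_kinship(tab4)
  bf <- bf_loiselle(tab4$geno[, c(1, 3)], tab4$geno[, c(2, 4)])
  expect_equal(unname(kin$Fij), bf, tolerance = 1e-12)
  # with missing data
  tab <- random_table(n = 7, loci = 3, alleles = 4, miss = 0.2, seed = 92)
  kin2 <- loiselle_kinship(tab)
  bf2 <- bf_loiselle(tab$geno[, c(1, 3, 5)], tab$geno[, c(2, 4, 6)])
  expect_equal(unname(kin2$Fij), bf2, tolerance = 1e-12)
})

test_that("mean kinship over the reference sample is near zero", {
  tab <- simulate_demes(deme_params(k = 1, f = 0.2, n_alleles = 6,
                                    n_per_deme = 60, loci = 10, seed = 93))
  kin <- loiselle_kinship(tab)
  expect_lt(abs(mean(kin$Fij[upper.tri(kin$Fij)])), 0.02)
})

test_that("parent-offspring pairs have kinship ~ 0.25", {
  p <- ibd_params(side = 2000, density = 2.5e-4, sigma_s = 400, sigma_p = 450,
                  loci = 10, mu = 1e-3, generations = 60, seed = 94)
  sim <- simulate_ibd(p, keep_parents = TRUE)
  comb <- genotype_table(rbind(sim$table$samples, sim$parents$samples),
                         rbind(sim$table$geno, sim$parents$geno),
                         sim$table$loci, "planar")
  kin <- loiselle_kinship(comb)
  n <- n_samples(sim$table)
  po <- kin$Fij[cbind(seq_len(n), n + sim$mother)]
  expect_lt(abs(mean(po) - 0.25), 0.05)
})

test_that("kinship-distance analysis: Sp identity, classes, exclusions", {
  sim <- simulate_ibd(ibd_params(side = 1000, density = 5e-4, sigma_s = 30,
                                 sigma_p = 60, loci = 8, mu = 1e-3,
                                 generations = 120, seed = 95))
  kin <- loiselle_kinship(sim$table)
  dm <- pairwise_distances(sim$table)
  sgs <- kinship_distance_analysis(kin, dm, n_perm = 99, seed = 1)
  expect_equal(sgs$Sp, -sgs$b_log / (1 - sgs$F1), tolerance = 1e-12)
  expect_equal(sum(sgs$classes$n_pairs), sgs$n_pairs)
  expect_true(is.finite(sgs$Sp_SE) && sgs$Sp_SE >= 0)
  # scale invariance: slope of F on ln(c*d) is the slope on ln(d)
  sgs2 <- kinship_distance_analysis(kin, dm * 7,
                                    classes = distance_classes(dm * 7),
                                    n_perm = 0, jackknife = FALSE)
  expect_equal(sgs2$b_log, sgs$b_log, tolerance = 1e-10)
  # Sp needs the same class definition for F1; rescale classes accordingly
  sgs3 <- kinship_distance_analysis(kin, dm * 7,
                                    classes = sgs$classes$upper_m * 7,
                                    n_perm = 0, jackknife = FALSE,
                                    fn_radius = 700)
  expect_equal(sgs3$Sp, sgs$Sp, tolerance = 1e-10)
  # all pairs at one distance -> regression undefined
  dm0 <- matrix(5, 4, 4); diag(dm0) <- 0
  kin4 <- loiselle_kinship(random_table(n = 4, loci = 2, miss = 0, seed = 9))
  expect_error(
    suppressWarnings(
      kinship_distance_analysis(kin4, dm0, classes = c(10), n_perm = 0,
                                jackknife = FALSE, min_pairs_warn = 0)),
    "identical distance")
})

test_that("location permutation test flags true structure, not noise", {
  sim <- simulate_ibd(ibd_params(side = 1000, density = 0.002, sigma_s = 30,
                                 sigma_p = 60, loci = 10, mu = 1e-3,
                                 generations = 300, seed = 96),
                      sample_n = 150)
  kin <- loiselle_kinship(sim$table)
  dm <- pairwise_distances(sim$table)
  sgs <- kinship_distance_analysis(kin, dm, n_perm = 199, seed = 2,
                                   jackknife = FALSE)
  expect_gt(sgs$Sp, 0)
  expect_lt(sgs$perm_p, 0.05)
  # destroy the structure by shuffling coordinates: p should not be small
  prm <- withr::with_seed(97, sample.int(150))
  sgs0 <- kinship_distance_analysis(kin, dm[prm, prm], n_perm = 199,
                                    seed = 3, jackknife = FALSE)
  expect_gt(sgs0$perm_p, 0.05)
})

test_that("dispersal_step closed form and estimate_sigma_g bookkeeping", {
  st <- dispersal_step(-0.005, 0.05, 9e-4)
  expect_equal(st$Nb, 190)
  expect_equal(st$sigma_g, sqrt(190 / (4 * pi * 9e-4)))
  expect_error(dispersal_step(0.002, 0.05, 9e-4))
  # converged estimates satisfy Nb = 4 pi De sigma^2 exactly
  sim <- simulate_ibd(ibd_params(side = 1000, density = 0.002, sigma_s = 30,
                                 sigma_p = 60, loci = 10, mu = 1e-3,
                                 generations = 300, seed = 98),
                      sample_n = 200)
  kin <- loiselle_kinship(sim$table)
  dm <- pairwise_distances(sim$table)
  est <- estimate_sigma_g(kin, dm, De = 0.002, max_distance = 500,
                          tol = 0.01)
  expect_true(est$converged)
  expect_equal(est$Nb, 4 * pi * est$De * est$sigma_g^2, tolerance = 1e-9)
  expect_gt(est$sigma_g, 0)
})

test_that("non-convergence is reported, never thrown", {
  # panmictic genotypes with random coordinates: no isolation by distance
  tab <- simulate_demes(deme_params(k = 1, f = 0.2, n_alleles = 5,
                                    n_per_deme = 80, loci = 10, seed = 99))
  tab$samples$x <- withr::with_seed(1, runif(80, 0, 1000))
  tab$samples$y <- withr::with_seed(2, runif(80, 0, 1000))
  kin <- loiselle_kinship(tab)
  dm <- pairwise_distances(tab)
  est <- tryCatch(estimate_sigma_g(kin, dm, De = 0.002),
                  error = function(e) "threw")
  expect_s3_class(est, "dispersal_estimate")
  # under the null roughly half of datasets have b >= 0; force one
  kin$Fij[] <- 0.01  # flat kinship -> slope exactly 0 within range
  est0 <- estimate_sigma_g(kin, dm, De = 0.002)
  expect_false(est0$converged)
})

test_that("validity-window warning fires for large mu", {
  sim <- simulate_ibd(ibd_params(side = 1000, density = 0.002, sigma_s = 30,
                                 sigma_p = 60, loci = 10, mu = 1e-3,
                                 generations = 300, seed = 98),
                      sample_n = 200)
  kin <- loiselle_kinship(sim$table)
  dm <- pairwise_distances(sim$table)
  expect_warning(
    estimate_sigma_g(kin, dm, De = 0.002, max_distance = 500, tol = 0.01,
                     mu = 0.01),
    "validity")
})

test_that("density scenarios reproduce fixed fractions in both units", {
  sc <- density_scenarios(18)
  expect_equal(sc$De_per_ha, c(9, 4.5, 1.8))
  expect_equal(sc$De_per_m2, c(9e-4, 4.5e-4, 1.8e-4))
  expect_equal(density_scenarios(7, 1)$De_per_ha, 7)
})
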