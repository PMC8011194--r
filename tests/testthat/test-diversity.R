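make_freqs <- function(...) {
  # build an allele_freqs object from genotype rows per locus
  tabs <- list(...)
  n <- max(vapply(tabs, nrow, integer(1)))
  geno <- do.call(cbind, tabs)
  genotype_table(data.frame(sample_id = sprintf("s%d", seq_len(n)),
                            x = seq_len(n), y = seq_len(n)),
                 geno, sprintf("L%d", seq_along(tabs))) |>
    allele_frequencies()
}

test_that("expected heterozygosity matches the unbiased formula", {
  # gene copies {A,A,B,B}: He = (4/3)(1 - 0.5)
  fr <- make_freqs(matrix(c(1L, 1L, 2L, 2L), 2, byrow = TRUE))
  expect_equal(expected_heterozygosity(fr)$mean, (4 / 3) * 0.5)
  # monomorphic locus
  fr2 <- make_freqs(matrix(c(5L, 5L, 5L, 5L), 2, byrow = TRUE))
  expect_equal(expected_heterozygosity(fr2)$mean, 0)
  # all copies distinct: He -> 1
  fr3 <- make_freqs(matrix(as.integer(1:20), 10, 2, byrow = TRUE))
  expect_gt(expected_heterozygosity(fr3)$mean, 0.99)
})

test_that("observed heterozygosity is the fraction of het genotypes", {
  s <- data.frame(sample_id = c("a", "b"), x = 0:1, y = 0:1)
  tab <- genotype_table(s, matrix(c(1L, 2L, 1L, 1L), 2, byrow = TRUE), "L1")
  expect_equal(observed_heterozygosity(tab)$mean, 0.5)
  hom <- genotype_table(s, matrix(c(1L, 1L, 2L, 2L), 2, byrow = TRUE), "L1")
  expect_equal(observed_heterozygosity(hom)$mean, 0)
  het <- genotype_table(s, matrix(c(1L, 2L, 1L, 3L), 2, byrow = TRUE), "L1")
  expect_equal(observed_heterozygosity(het)$mean, 1)
})

test_that("effective allele number", {
  # copies {1,1,2,3}: p = (0.5, 0.25, 0.25) -> 1 / 0.375
  fr <- make_freqs(matrix(c(1L, 1L, 2L, 3L), 2, byrow = TRUE))
  expect_equal(effective_allele_number(fr)$mean, 8 / 3)
  mono <- make_freqs(matrix(c(5L, 5L, 5L, 5L), 2, byrow = TRUE))
  expect_equal(effective_allele_number(mono)$mean, 1)
  # m equifrequent alleles -> m
  eq <- make_freqs(matrix(c(1L, 2L, 3L, 4L), 2, byrow = TRUE))
  expect_equal(effective_allele_number(eq)$mean, 4)
})

test_that("allelic richness: hand value, identities, monotonicity, oracle", {
  # n = 4 copies, counts {3,1}, k = 2 -> 1.5
  fr <- make_freqs(matrix(c(1L, 1L, 1L, 2L), 2, byrow = TRUE))
  expect_equal(allelic_richness(fr, 2)$mean, 1.5)
  # k = n -> observed allele count; k = 1 -> 1
  expect_equal(allelic_richness(fr, 4)$mean, 2)
  expect_equal(allelic_richness(fr, 1)$mean, 1)
  expect_error(allelic_richness(fr, 5), "L1")
  # enumeration oracle + monotone in k on a random fixture
  tab <- random_table(n = 6, loci = 1, alleles = 4, miss = 0, seed = 31)
  fr2 <- allele_frequencies(tab)
  copies <- c(tab$geno[, 1], tab$geno[, 2])
  prev <- 0
  for (k in 1:12) {
    ar <- allelic_richness(fr2, k)$mean
    expect_equal(ar, bf_ar(copies, k), tolerance = 1e-12)
    expect_gte(ar, prev)
    prev <- ar
  }
})

test_that("diversity statistics equal brute-force enumeration to 1e-12", {
  for (seed in c(41, 42, 43)) {
    tab <- random_table(n = 9, loci = 4, alleles = 5, miss = 0.15,
                        seed = seed)
    fr <- allele_frequencies(tab)
    a1 <- tab$geno[, seq(1, 7, 2)]
    a2 <- tab$geno[, seq(2, 8, 2)]
    he <- vapply(seq_len(4), function(l) {
      copies <- c(a1[, l], a2[, l]); bf_he(copies[!is.na(copies)])
    }, numeric(1))
    expect_equal(expected_heterozygosity(fr)$mean, mean(he),
                 tolerance = 1e-12)
    nae <- vapply(seq_len(4), function(l) {
      copies <- c(a1[, l], a2[, l]); bf_nae(copies[!is.na(copies)])
    }, numeric(1))
    expect_equal(effective_allele_number(fr)$mean, mean(nae),
                 tolerance = 1e-12)
    ho <- vapply(seq_len(4), function(l)
      mean((a1[, l] != a2[, l])[!is.na(a1[, l])]), numeric(1))
    expect_equal(observed_heterozygosity(tab)$mean, mean(ho),
                 tolerance = 1e-12)
    fi <- inbreeding_coefficient(tab, n_perm = 0)
    expect_equal(fi$Fi, bf_fi(a1, a2), tolerance = 1e-12)
  }
})

test_that("Fi is near zero under HWE and 1 under complete homozygosity", {
  hwe <- simulate_demes(deme_params(k = 1, f = 0.2, n_alleles = 6,
                                    n_per_deme = 200, loci = 10, seed = 55))
  fi <- inbreeding_coefficient(hwe, n_perm = 200, seed = 1)
  expect_lt(abs(fi$Fi), 0.05)
  expect_gt(fi$p_two_sided, 0.05)
  # fully selfed limit: polymorphic but no heterozygote
  s <- data.frame(sample_id = sprintf("s%d", 1:6), x = 1:6, y = 1:6)
  g <- cbind(rep(c(1L, 2L, 3L), each = 2), rep(c(1L, 2L, 3L), each = 2))
  tab <- genotype_table(s, g, "L1")
  expect_equal(inbreeding_coefficient(tab, n_perm = 0)$Fi, 1)
})

test_that("monomorphic loci contribute nothing to Fi (He=0 => Ho=0)", {
  tab <- random_table(n = 10, loci = 2, alleles = 3, miss = 0, seed = 77)
  tab2 <- tab
  tab2$geno <- cbind(tab$geno, matrix(9L, 10, 2))
  tab2$loci <- c(tab$loci, "MONO")
  tab2$geno <- genotype_table(tab$samples, tab2$geno, tab2$loci)$geno
  fr <- allele_frequencies(genotype_table(tab$samples, tab2$geno, tab2$loci))
  expect_equal(expected_heterozygosity(fr)$per_locus[["MONO"]], 0)
  expect_equal(observed_heterozygosity(
    genotype_table(tab$samples, tab2$geno, tab2$loci))$per_locus[["MONO"]], 0)
  expect_equal(inbreeding_coefficient(tab, n_perm = 0)$Fi,
               inbreeding_coefficient(
                 genotype_table(tab$samples, tab2$geno, tab2$loci),
                 n_perm = 0)$Fi,
               tolerance = 1e-12)
})

test_that("diversity_summary assembles the per-group panel", {
  tab <- simulate_demes(deme_params(k = 2, f = 0.25, n_alleles = 5,
                                    n_per_deme = 30, loci = 6, seed = 66))
  div <- diversity_summary(tab, n_perm = 50, seed = 2)
  expect_equal(div$group, c("deme1", "deme2"))
  expect_true(all(div$He >= 0 & div$He <= 1))
  expect_true(all(div$Ho >= 0 & div$Ho <= 1))
  expect_true(all(div$NAe >= 1))
  expect_true(all(div$AR >= 1 & div$AR <= div$k))
  expect_true(all(abs(div$Fi) <= 1))
})
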