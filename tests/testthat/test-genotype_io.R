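test_that("CSV and SPAGeDi round trips are lossless", {
  tab <- tiny_table()
  expect_equal(n_samples(tab), 3L)
  expect_equal(n_loci(tab), 2L)

  csv <- withr::local_tempfile(fileext = ".csv")
  write_genotypes(tab, csv)
  back <- read_genotypes(csv)
  expect_identical(back$geno, tab$geno)
  expect_identical(back$samples, tab$samples)
  expect_identical(back$loci, tab$loci)

  spa <- withr::local_tempfile(fileext = ".txt")
  write_genotypes(tab, spa, format = "spagedi")
  back2 <- read_genotypes(spa, format = "spagedi")
  expect_identical(back2$geno, tab$geno)
  expect_equal(back2$samples$x, tab$samples$x)

  # bigger random table with missing data
  big <- random_table(n = 20, loci = 5, miss = 0.15, seed = 4)
  for (fmt in c("csv", "spagedi")) {
    f <- withr::local_tempfile()
    write_genotypes(big, f, format = fmt)
    expect_identical(read_genotypes(f, format = fmt)$geno, big$geno)
  }
})

test_that("table validation rejects malformed input", {
  s <- data.frame(sample_id = c("a", "b"), x = 0:1, y = 0:1)
  # one-allele genotype
  expect_error(
    genotype_table(s, matrix(c(105L, NA, 101L, 102L), 2, byrow = TRUE), "L1"),
    "one allele")
  # duplicate sample id
  s2 <- data.frame(sample_id = c("a", "a"), x = 0:1, y = 0:1)
  expect_error(
    genotype_table(s2, matrix(c(1L, 1L, 2L, 2L), 2, byrow = TRUE), "L1"),
    "duplicate sample_id")
  # negative allele
  expect_error(
    genotype_table(s, matrix(c(-1L, 2L, 1L, 2L), 2, byrow = TRUE), "L1"),
    "positive")
  # odd allele column count in CSV
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample_id,x,y,group,L1_1", "a,0,0,,105"), f)
  expect_error(read_genotypes(f), "odd|pairs")
  # partial genotype in CSV names the line
  f2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample_id,x,y,group,L1_1,L1_2",
               "a,0,0,,105,107", "b,0,0,,105,"), f2)
  expect_error(read_genotypes(f2), "one allele")
})

test_that("unordered allele pairs are canonical and 0 means missing", {
  s <- data.frame(sample_id = c("a", "b"), x = 0:1, y = 0:1)
  t1 <- genotype_table(s, matrix(c(103L, 101L, 0L, 0L), 2, byrow = TRUE), "L1")
  expect_equal(unname(t1$geno[1, ]), c(101L, 103L))
  expect_true(all(is.na(t1$geno[2, ])))
})

test_that("STRUCTURE export writes two -9-coded rows per individual", {
  f <- withr::local_tempfile()
  write_structure(tiny_table(), f)
  lines <- readLines(f)
  expect_length(lines, 1 + 2 * 3)
  # s3 rows: L1 = 101/101, L2 missing -> -9 in both rows
  expect_match(lines[6], "^s3\t[0-9]+\t101\t-9$")
  expect_match(lines[7], "^s3\t[0-9]+\t101\t-9$")
})

test_that("filter_min_typed_loci applies the 6-of-10 boundary rule", {
  n <- 3
  g <- matrix(NA_integer_, n, 20)
  # s1 typed at 5 loci, s2 at 6 loci, s3 at 10
  for (l in 1:10) {
    if (l <= 5) g[1, c(2 * l - 1, 2 * l)] <- c(1L, 2L)
    if (l <= 6) g[2, c(2 * l - 1, 2 * l)] <- c(1L, 2L)
    g[3, c(2 * l - 1, 2 * l)] <- c(1L, 2L)
  }
  tab <- genotype_table(
    data.frame(sample_id = c("s5", "s6", "s10"), x = 1:3, y = 1:3),
    g, sprintf("L%d", 1:10))
  kept <- filter_min_typed_loci(tab, 0.6)
  expect_identical(kept$samples$sample_id, c("s6", "s10"))
  expect_identical(filter_min_typed_loci(tab, 0.01)$samples$sample_id,
                   tab$samples$sample_id)
  # every sample of tiny_table misses nothing except s3; drop all by
  # requiring full typing on a table where everyone has a gap
  gappy <- subset_samples(tab, 1:2)  # s5 (5/10), s6 (6/10)
  expect_warning(out <- filter_min_typed_loci(gappy, 0.9), "no sample")
  expect_equal(n_samples(out), 0L)
})

test_that("detect_duplicates finds exact matches on shared loci", {
  tab <- random_table(n = 6, loci = 10, miss = 0, seed = 9)
  # make s6 a clone of s1, and s5 a near-clone differing at locus 1
  tab$geno[6, ] <- tab$geno[1, ]
  tab$geno[5, ] <- tab$geno[1, ]
  tab$geno[5, 1:2] <- c(40L, 41L)
  dup <- detect_duplicates(tab)
  expect_true(any(dup$id1 == "s01" & dup$id2 == "s06" & dup$identical))
  expect_false(any(dup$id1 == "s01" & dup$id2 == "s05"))
  all_p <- detect_duplicates(tab, all_pairs = TRUE)
  near <- all_p[all_p$id1 == "s01" & all_p$id2 == "s05", ]
  expect_true(near$coefficient < 1)
  # overlap floor: mask loci so only 3 shared -> excluded
  tab2 <- tab
  tab2$geno[1, 7:20] <- NA_integer_
  dup2 <- detect_duplicates(tab2, min_shared_loci = 5)
  expect_false(any(dup2$id1 == "s01" | dup2$id2 == "s01"))
})

test_that("grid_subsample caps cells, is deterministic and idempotent", {
  n <- 8
  tab <- genotype_table(
    data.frame(sample_id = sprintf("s%d", 1:n),
               x = c(rep(0.005, 5), 0.05, 0.06, 0.07),
               y = c(rep(0.005, 5), 0.05, 0.06, 0.07)),
    matrix(rep(c(1L, 2L), n), n, 2, byrow = TRUE), "L1",
    coord_system = "geographic")
  out <- grid_subsample(tab, 0.01, 3L, seed = 42)
  expect_equal(n_samples(out), 3 + 3)  # 5 -> 3 in the dense cell
  expect_identical(grid_subsample(tab, 0.01, 3L, seed = 42)$samples,
                   out$samples)
  # idempotent: already <= 3 per cell
  expect_identical(grid_subsample(out, 0.01, 3L, seed = 1)$samples,
                   out$samples)
  # all cells small -> unchanged
  sparse <- subset_samples(tab, 6:8)
  expect_identical(grid_subsample(sparse, 0.01, 3L, seed = 7)$samples,
                   sparse$samples)
  planar <- tiny_table()
  expect_error(grid_subsample(planar, 0.01, 3L, seed = 1), "geographic")
})

test_that("allele_frequencies counts gene copies and respects groups", {
  s <- data.frame(sample_id = c("a", "b"), x = 0:1, y = 0:1)
  tab <- genotype_table(s, matrix(c(1L, 1L, 1L, 2L), 2, byrow = TRUE), "L1")
  fr <- allele_frequencies(tab)
  expect_equal(unname(fr$freq$L1), c(0.75, 0.25))
  expect_equal(fr$n, 4L)
  mono <- genotype_table(s, matrix(c(7L, 7L, 7L, 7L), 2, byrow = TRUE), "L1")
  expect_equal(unname(allele_frequencies(mono)$freq$L1), 1)
  expect_error(allele_frequencies(tiny_table(), group = "nope"), "no samples")
})

test_that("union frequencies are the copy-count-weighted group average", {
  tab <- random_table(n = 12, loci = 3, miss = 0.2,
                      groups = c("A", "B"), seed = 11)
  fu <- allele_frequencies(tab)
  fa <- allele_frequencies(tab, group = "A")
  fb <- allele_frequencies(tab, group = "B")
  for (l in fu$loci) {
    la <- match(l, fa$loci); lb <- match(l, fb$loci)
    alleles <- names(fu$freq[[l]])
    get <- function(fr, li) {
      v <- stats::setNames(rep(0, length(alleles)), alleles)
      if (!is.na(li)) v[names(fr$freq[[li]])] <- fr$freq[[li]]
      v
    }
    na <- if (is.na(la)) 0 else fa$n[la]
    nb <- if (is.na(lb)) 0 else fb$n[lb]
    expect_equal(unname(fu$freq[[l]]),
                 unname((na * get(fa, la) + nb * get(fb, lb)) / (na + nb)),
                 tolerance = 1e-12)
  }
})

test_that("pairwise distances: euclidean, haversine, errors", {
  expect_equal(pairwise_distances(tiny_table())["s1", "s2"], 5)
  expect_equal(pairwise_distances(tiny_table())["s1", "s1"], 0)
  geo <- genotype_table(
    data.frame(sample_id = c("p", "q"), x = c(0, 1), y = c(0, 0)),
    matrix(c(1L, 1L, 1L, 1L), 2, byrow = TRUE), "L1",
    coord_system = "geographic")
  # 1 degree on the equator: R * pi/180
  expect_equal(pairwise_distances(geo)["p", "q"], 6371000 * pi / 180,
               tolerance = 1e-9)
  bad <- tiny_table()
  bad$samples$x[2] <- NA
  expect_error(pairwise_distances(bad), "s2")
})
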