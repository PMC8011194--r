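# fixtures built in code

# tiny hand-written table: 3 samples, 2 loci, one missing genotype
tiny_table <- function() {
  genotype_table(
    data.frame(sample_id = c("s1", "s2", "s3"),
               x = c(0, 3, 0), y = c(0, 4, 1),
               group = c("g1", "g1", "g2"), stringsAsFactors = FALSE),
    matrix(c(101L, 103L, 105L, 105L,
             103L, 101L, 105L, 107L,
             101L, 101L, NA, NA), nrow = 3, byrow = TRUE),
    c("L1", "L2"))
}

# random small table with optional missingness, planar coordinates
random_table <- function(n = 8, loci = 3, alleles = 4, miss = 0.1,
                         groups = NULL, seed = 1) {
  withr::with_seed(seed, {
    g <- matrix(sample(10:(9 + alleles), n * 2 * loci, replace = TRUE),
                n, 2 * loci)
    if (miss > 0) {
      hit <- matrix(runif(n * loci) < miss, n, loci)
      for (l in seq_len(loci)) {
        g[hit[, l], 2 * l - 1] <- NA
        g[hit[, l], 2 * l] <- NA
      }
    }
    genotype_table(
      data.frame(sample_id = sprintf("s%02d", seq_len(n)),
                 x = runif(n, 0, 100), y = runif(n, 0, 100),
                 group = if (is.null(groups)) NA_character_
                         else rep_len(groups, n),
                 stringsAsFactors = FALSE),
      g, sprintf("L%d", seq_len(loci)))
  })
}
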