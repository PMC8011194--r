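#' Expected heterozygosity (unbiased)
#'
#' Per-locus Nei's unbiased expected heterozygosity
#' `He_l = n_l / (n_l - 1) * (1 - sum(p^2))` over the `n_l` observed gene
#' copies, and the unweighted multilocus mean. Loci with fewer than 2 copies
#' are excluded with a warning.
#'
#' @param freqs an [allele_frequencies()] object.
#' @return list with `per_locus` (named vector) and `mean`.
#' @export
expected_heterozygosity <- function(freqs) {
  ok <- freqs$n >= 2L
  if (any(!ok))
    warning("loci with < 2 gene copies excluded: ",
            paste(freqs$loci[!ok], collapse = ", "))
  he <- vapply(which(ok), function(l) {
    n <- freqs$n[l]
    (n / (n - 1)) * (1 - sum(freqs$freq[[l]]^2))
  }, numeric(1))
  names(he) <- freqs$loci[ok]
  list(per_locus = he, mean = mean(he))
}

#' Observed heterozygosity
#'
#' Fraction of typed genotypes carrying two distinct alleles, per locus, and
#' the unweighted multilocus mean.
#'
#' @param table a [genotype_table()].
#' @param group optional group label(s).
#' @return list with `per_locus` and `mean`.
#' @export
observed_heterozygosity <- function(table, group = NULL) {
  if (!is.null(group)) table <- subset_samples(table, group = group)
  a1 <- allele_matrix(table, 1L)
  a2 <- allele_matrix(table, 2L)
  ho <- colMeans(a1 != a2, na.rm = TRUE)
  names(ho) <- table$loci
  ho <- ho[!is.nan(ho)]
  list(per_locus = ho, mean = mean(ho))
}

#' Effective number of alleles
#'
#' `NAe_l = 1 / sum(p^2)` per locus; multilocus value is the unweighted mean.
#'
#' @param freqs an [allele_frequencies()] object.
#' @return list with `per_locus` and `mean`.
#' @export
effective_allele_number <- function(freqs) {
  nae <- vapply(freqs$freq, function(p) 1 / sum(p^2), numeric(1))
  list(per_locus = nae, mean = mean(nae))
}

#' Rarefied allelic richness
#'
#' Expected number of distinct alleles among `k` gene copies drawn without
#' replacement from the observed copies (hurlbert rarefaction):
#' `AR_l(k) = sum_a [1 - choose(n_l - n_a, k) / choose(n_l, k)]`, computed in
#' log space.
#'
#' @param freqs an [allele_frequencies()] object.
#' @param k standardized number of gene copies; must not exceed any locus's
#'   observed copy count.
#' @return list with `per_locus`, `mean`, and `k`.
#' @export
allelic_richness <- function(freqs, k) {
  stopifnot(k >= 1)
  bad <- freqs$n < k
  if (any(bad))
    stop("k = ", k, " exceeds gene copies at locus: ",
         paste(freqs$loci[bad], collapse = ", "))
  ar <- vapply(seq_along(freqs$freq), function(l) {
    n <- freqs$n[l]
    na <- freqs$counts[[l]]
    sum(1 - exp(lchoose(n - na, k) - lchoose(n, k)))
  }, numeric(1))
  names(ar) <- freqs$loci
  list(per_locus = ar, mean = mean(ar), k = k)
}

#' Multilocus inbreeding coefficient with permutation test
#'
#' Weir & Cockerham-type within-group f: per-locus, per-allele variance
#' components (among individuals `b`, within individuals `c`) are summed
#' over alleles and loci before the ratio `Fi = b / (b + c)`. Significance
#' is assessed by permuting gene copies among individuals within the group
#' (re-pairing copies at each locus independently), which enforces
#' Hardy-Weinberg expectations.
#'
#' @param table a [genotype_table()].
#' @param group optional group label(s).
#' @param n_perm number of permutations (0 disables the test).
#' @param seed RNG seed for the permutations.
#' @return list with `Fi`, `p_two_sided`, `p_one_sided` (upper tail),
#'   `n_perm`.
#' @export
inbreeding_coefficient <- function(table, group = NULL, n_perm = 10000L,
                                   seed = 1L) {
  if (!is.null(group)) table <- subset_samples(table, group = group)
  if (n_samples(table) < 2L) stop("need at least 2 individuals")
  obs <- fi_components(table)
  fi <- obs["b"] / (obs["b"] + obs["c"])
  if (n_perm > 0L) {
    perm <- withr::with_seed(seed, vapply(seq_len(n_perm), function(r) {
      co <- fi_components(permute_copies(table))
      co["b"] / (co["b"] + co["c"])
    }, numeric(1)))
    p_up <- (sum(perm >= fi) + 1) / (n_perm + 1)
    p_lo <- (sum(perm <= fi) + 1) / (n_perm + 1)
    p2 <- min(1, 2 * min(p_up, p_lo))
  } else {
    p_up <- p2 <- NA_real_
  }
  list(Fi = unname(fi), p_two_sided = p2, p_one_sided = p_up,
       n_perm = n_perm)
}

# summed (b, c) components over loci and alleles for a single group, using
# the closed per-allele form of the nested-ANOVA components (equal to
# varcomp_copies on allele indicators to machine precision)
fi_components <- function(table) {
  b <- 0; cc <- 0
  for (l in seq_len(n_loci(table))) {
    a1 <- table$geno[, 2L * l - 1L]; a2 <- table$geno[, 2L * l]
    typed <- !is.na(a1)
    n <- sum(typed)
    if (n < 2L) next
    a1 <- a1[typed]; a2 <- a2[typed]
    u <- unique(c(a1, a2))
    p <- (tabulate(match(a1, u), length(u)) +
          tabulate(match(a2, u), length(u))) / (2 * n)
    het <- a1 != a2
    h <- (tabulate(match(a1[het], u), length(u)) +
          tabulate(match(a2[het], u), length(u))) / n
    b <- b + sum(n / (n - 1) * (p * (1 - p) - (2 * n - 1) / (4 * n) * h))
    cc <- cc + sum(h / 2)
  }
  c(b = b, c = cc)
}

# re-pair gene copies at each locus independently (HWE null)
permute_copies <- function(table) {
  g <- table$geno
  for (l in seq_len(n_loci(table))) {
    a1 <- g[, 2L * l - 1L]; a2 <- g[, 2L * l]
    typed <- which(!is.na(a1))
    copies <- sample(c(a1[typed], a2[typed]))
    g[typed, 2L * l - 1L] <- copies[seq_along(typed)]
    g[typed, 2L * l] <- copies[length(typed) + seq_along(typed)]
  }
  genotype_table(table$samples, g, table$loci, table$coord_system)
}

#' Per-group diversity summary
#'
#' Computes the standard multilocus diversity panel per group: sample size,
#' effective number of alleles (NAe), rarefied allelic richness AR(k),
#' expected (He) and observed (Ho) heterozygosity, and the inbreeding
#' coefficient Fi with permutation p-value.
#'
#' @param table a [genotype_table()] with group labels.
#' @param k gene copies for rarefaction; default: largest k valid in every
#'   group (smallest per-locus copy count).
#' @param n_perm permutations for the Fi test.
#' @param seed RNG seed.
#' @param groups groups to summarize (default: all labelled).
#' @return data.frame, one row per group, columns `group, n, NAe, AR, k, He,
#'   Ho, Fi, Fi_p`.
#' @export
diversity_summary <- function(table, k = NULL, n_perm = 1000L, seed = 1L,
                              groups = NULL) {
  if (is.null(groups))
    groups <- sort(unique(stats::na.omit(table$samples$group)))
  rows <- lapply(groups, function(g) {
    sub <- subset_samples(table, group = g)
    fr <- allele_frequencies(sub)
    kk <- if (is.null(k)) min(fr$n) else k
    fi <- inbreeding_coefficient(sub, n_perm = n_perm, seed = seed)
    data.frame(group = g, n = n_samples(sub),
               NAe = effective_allele_number(fr)$mean,
               AR = allelic_richness(fr, kk)$mean, k = kk,
               He = expected_heterozygosity(fr)$mean,
               Ho = observed_heterozygosity(sub)$mean,
               Fi = fi$Fi, Fi_p = fi$p_two_sided,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
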