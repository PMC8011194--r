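#' Pairwise FST (Weir & Cockerham theta)
#'
#' For every pair of groups, per-locus, per-allele variance components
#' (among groups `a`, among individuals within groups `b`, within
#' individuals `c`) are computed by the nested gene-copy ANOVA — the Weir &
#' Cockerham (1984) estimator — and summed over alleles and loci before the
#' ratio `theta = a / (a + b + c)`. Negative estimates are reported as
#' computed. Loci at which either group has fewer than 2 typed individuals
#' are skipped for that pair; a pair with no usable locus gets `NA`.
#'
#' @param table a [genotype_table()].
#' @param groups ordered group labels (default: all labelled groups).
#' @return Symmetric numeric matrix of pairwise theta, zero diagonal.
#' @export
pairwise_fst <- function(table, groups = NULL) {
  pairwise_theta(table, groups, statistic = "fst")
}

#' Pairwise RST (allele-size variance components)
#'
#' Slatkin-type RST: the same nested gene-copy ANOVA as [pairwise_fst()] but
#' applied to allele sizes (one quantitative value per gene copy) instead of
#' allele indicators, components summed over loci before the ratio. With
#' exactly two alleles one repeat unit apart at every locus, RST equals FST
#' identically.
#'
#' @inheritParams pairwise_fst
#' @return Symmetric numeric matrix of pairwise RST, zero diagonal.
#' @export
pairwise_rst <- function(table, groups = NULL) {
  pairwise_theta(table, groups, statistic = "rst")
}

pairwise_theta <- function(table, groups, statistic) {
  if (is.null(groups))
    groups <- sort(unique(stats::na.omit(table$samples$group)))
  if (length(groups) < 2L) stop("need at least 2 groups")
  K <- length(groups)
  out <- matrix(0, K, K, dimnames = list(groups, groups))
  for (i in seq_len(K - 1L)) {
    for (j in (i + 1L):K) {
      comp <- theta_components(table, c(groups[i], groups[j]), statistic)
      out[i, j] <- out[j, i] <-
        if (is.null(comp)) NA_real_
        else comp["a"] / (comp["a"] + comp["b"] + comp["c"])
    }
  }
  out
}

# summed (a,b,c) over loci (and alleles, for fst) for the given group pair;
# size_map: optional list per locus mapping distinct allele states to
# (permuted) size values, used by the allele-size permutation test
theta_components <- function(table, groups, statistic, size_map = NULL) {
  group_of <- table$samples$group
  tot <- c(a = 0, b = 0, c = 0)
  used <- FALSE
  for (l in seq_len(n_loci(table))) {
    lc <- locus_copies(table, l, group_of, groups)
    if (is.null(lc)) next
    if (statistic == "fst") {
      for (al in unique(lc$y)) {
        vc <- varcomp_copies(as.numeric(lc$y == al), lc$group)
        tot <- tot + vc
      }
    } else {
      y <- if (is.null(size_map)) as.numeric(lc$y)
           else unname(size_map[[l]][as.character(lc$y)])
      vc <- varcomp_copies(y, lc$group)
      tot <- tot + vc
    }
    used <- TRUE
  }
  if (!used) NULL else tot
}

#' Allele-size permutation test for phylogeographic signal
#'
#' Tests, for each pair of groups, whether stepwise mutations contribute to
#' differentiation: allele size values are shuffled among the distinct
#' allele states within each locus (genotype identities kept, sizes
#' reassigned) and RST is recomputed for each permutation. The one-sided
#' p-value is the proportion of permuted RST values greater than or equal to
#' the observed RST, with the (r+1)/(n+1) correction. Under pure drift the
#' permuted distribution is that of FST-like statistics, so a significant
#' result means RST > FST.
#'
#' @inheritParams pairwise_fst
#' @param n_perm number of size permutations.
#' @param seed RNG seed.
#' @return list with `p` (matrix of one-sided p-values), `RST` (observed),
#'   and `n_perm`.
#' @export
allele_size_permutation_test <- function(table, groups = NULL,
                                         n_perm = 10000L, seed = 1L) {
  if (is.null(groups))
    groups <- sort(unique(stats::na.omit(table$samples$group)))
  if (length(groups) < 2L) stop("need at least 2 groups")
  sizes <- lapply(seq_len(n_loci(table)), function(l) {
    u <- sort(unique(stats::na.omit(c(table$geno[, 2L * l - 1L],
                                      table$geno[, 2L * l]))))
    stats::setNames(as.numeric(u), u)
  })
  if (all(lengths(sizes) < 2L))
    stop("fewer than 2 distinct alleles at every locus: test undefined")
  K <- length(groups)
  rst_obs <- pairwise_rst(table, groups)
  pmat <- matrix(NA_real_, K, K, dimnames = list(groups, groups))
  exceed <- matrix(0L, K, K)
  # precompute gene copies per (pair, locus): only sizes change per perm
  group_of <- table$samples$group
  pair_lc <- list()
  for (i in seq_len(K - 1L)) {
    for (j in (i + 1L):K) {
      pair_lc[[paste(i, j)]] <- lapply(seq_len(n_loci(table)), function(l) {
        lc <- locus_copies(table, l, group_of, c(groups[i], groups[j]))
        if (is.null(lc)) return(NULL)
        lc$state <- as.character(lc$y)
        lc
      })
    }
  }
  withr::with_seed(seed, {
    for (r in seq_len(n_perm)) {
      perm_map <- lapply(sizes, function(s) {
        stats::setNames(as.numeric(sample(s)), names(s))
      })
      for (i in seq_len(K - 1L)) {
        for (j in (i + 1L):K) {
          if (is.na(rst_obs[i, j])) next
          lcs <- pair_lc[[paste(i, j)]]
          tot <- c(a = 0, b = 0, c = 0)
          for (l in seq_along(lcs)) {
            if (is.null(lcs[[l]])) next
            tot <- tot + varcomp_copies(unname(perm_map[[l]][lcs[[l]]$state]),
                                        lcs[[l]]$group)
          }
          val <- tot["a"] / (tot["a"] + tot["b"] + tot["c"])
          if (val >= rst_obs[i, j]) exceed[i, j] <- exceed[i, j] + 1L
        }
      }
    }
  })
  for (i in seq_len(K - 1L)) {
    for (j in (i + 1L):K) {
      if (!is.na(rst_obs[i, j]))
        pmat[i, j] <- pmat[j, i] <- (exceed[i, j] + 1) / (n_perm + 1)
    }
  }
  diag(pmat) <- NA_real_
  list(p = pmat, RST = rst_obs, n_perm = n_perm)
}

#' Full differentiation analysis
#'
#' Pairwise FST and RST matrices plus the allele-size permutation test, in
#' one container (the Table-2-style result).
#'
#' @inheritParams allele_size_permutation_test
#' @return list of class `differentiation_result` with `groups`, `FST`,
#'   `RST`, `pRST_p`, `n_perm`.
#' @export
differentiation <- function(table, groups = NULL, n_perm = 10000L,
                            seed = 1L) {
  if (is.null(groups))
    groups <- sort(unique(stats::na.omit(table$samples$group)))
  fst <- pairwise_fst(table, groups)
  tst <- allele_size_permutation_test(table, groups, n_perm, seed)
  structure(list(groups = groups, FST = fst, RST = tst$RST,
                 pRST_p = tst$p, n_perm = n_perm),
            class = "differentiation_result")
}

#' @export
print.differentiation_result <- function(x, ...) {
  cat("differentiation_result:", length(x$groups), "groups,",
      x$n_perm, "allele-size permutations\n")
  m <- x$FST
  m[upper.tri(m)] <- x$RST[upper.tri(x$RST)]
  cat("FST below / RST above diagonal:\n")
  print(round(m, 3))
  invisible(x)
}
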