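# Independent brute-force oracles: deliberately naive implementations used
# only to verify the package's vectorized/closed-form routes. They share no
# code with R/.

# expected heterozygosity from raw gene copies at one locus
bf_he <- function(copies) {
  n <- length(copies)
  p <- table(copies) / n
  (n / (n - 1)) * (1 - sum(p^2))
}

bf_nae <- function(copies) {
  p <- table(copies) / length(copies)
  1 / sum(p^2)
}

# rarefied allelic richness by full enumeration of k-subsets
bf_ar <- function(copies, k) {
  subs <- utils::combn(length(copies), k)
  mean(apply(subs, 2L, function(ix) length(unique(copies[ix]))))
}

# naive nested ANOVA variance components on gene-copy values;
# a1, a2: per-individual allele values; grp: per-individual group
bf_varcomp <- function(y1, y2, grp) {
  n_ind <- length(y1)
  K <- length(unique(grp))
  yi <- (y1 + y2) / 2
  ybar <- mean(c(y1, y2))
  ss_wi <- 0; ss_ai <- 0; ss_ag <- 0
  yg <- sapply(unique(grp), function(g) mean(c(y1[grp == g], y2[grp == g])))
  names(yg) <- unique(grp)
  cg <- sapply(unique(grp), function(g) 2 * sum(grp == g))
  names(cg) <- unique(grp)
  for (i in seq_len(n_ind)) {
    ss_wi <- ss_wi + (y1[i] - yi[i])^2 + (y2[i] - yi[i])^2
    ss_ai <- ss_ai + 2 * (yi[i] - yg[as.character(grp[i])])^2
  }
  for (g in unique(grp))
    ss_ag <- ss_ag + cg[as.character(g)] * (yg[as.character(g)] - ybar)^2
  sig_c <- unname(ss_wi / n_ind)
  sig_b <- unname((ss_ai / (n_ind - K) - sig_c) / 2)
  if (K < 2) return(c(a = NA, b = sig_b, c = sig_c))
  C <- 2 * n_ind
  k1 <- (C - sum(cg^2) / C) / (K - 1)
  sig_a <- unname((ss_ag / (K - 1) - sig_c - 2 * sig_b) / k1)
  c(a = sig_a, b = sig_b, c = sig_c)
}

# single-group f (FIS) by naive ANOVA over allele indicators
bf_fi <- function(a1mat, a2mat) {
  b <- 0; cc <- 0
  for (l in seq_len(ncol(a1mat))) {
    typed <- !is.na(a1mat[, l])
    if (sum(typed) < 2) next
    y1 <- a1mat[typed, l]; y2 <- a2mat[typed, l]
    for (al in unique(c(y1, y2))) {
      vc <- bf_varcomp(as.numeric(y1 == al), as.numeric(y2 == al),
                       rep(1, sum(typed)))
      b <- b + vc["b"]; cc <- cc + vc["c"]
    }
  }
  unname(b / (b + cc))
}

# two-group theta via the printed Weir & Cockerham (1984) formulas
bf_fst_wc <- function(a1mat, a2mat, grp) {
  r <- 2
  gs <- unique(grp)
  A <- B <- C <- 0
  for (l in seq_len(ncol(a1mat))) {
    typed <- !is.na(a1mat[, l])
    y1 <- a1mat[typed, l]; y2 <- a2mat[typed, l]; g <- grp[typed]
    if (any(table(factor(g, levels = gs)) < 2)) next
    ni <- sapply(gs, function(x) sum(g == x))
    nbar <- mean(ni)
    nc <- (sum(ni) - sum(ni^2) / sum(ni)) / (r - 1)
    for (al in unique(c(y1, y2))) {
      pi <- sapply(gs, function(x) mean(c(y1[g == x], y2[g == x]) == al))
      hi <- sapply(gs, function(x)
        mean((y1[g == x] == al) != (y2[g == x] == al)))
      pbar <- sum(ni * pi) / sum(ni)
      hbar <- sum(ni * hi) / sum(ni)
      s2 <- sum(ni * (pi - pbar)^2) / ((r - 1) * nbar)
      a <- (nbar / nc) *
        (s2 - (1 / (nbar - 1)) *
           (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4))
      b <- (nbar / (nbar - 1)) *
        (pbar * (1 - pbar) - s2 * (r - 1) / r -
           hbar * (2 * nbar - 1) / (4 * nbar))
      A <- A + a; B <- B + b; C <- C + hbar / 2
    }
  }
  A / (A + B + C)
}

# two-group RST by naive ANOVA on allele sizes
bf_rst <- function(a1mat, a2mat, grp) {
  gs <- unique(grp)
  A <- B <- C <- 0
  for (l in seq_len(ncol(a1mat))) {
    typed <- !is.na(a1mat[, l])
    y1 <- a1mat[typed, l]; y2 <- a2mat[typed, l]; g <- grp[typed]
    if (any(table(factor(g, levels = gs)) < 2)) next
    vc <- bf_varcomp(as.numeric(y1), as.numeric(y2), g)
    A <- A + vc["a"]; B <- B + vc["b"]; C <- C + vc["c"]
  }
  unname(A / (A + B + C))
}

# Loiselle kinship by direct double loop over the published formula
bf_loiselle <- function(a1mat, a2mat) {
  n <- nrow(a1mat)
  L <- ncol(a1mat)
  freqs <- lapply(seq_len(L), function(l) {
    copies <- c(a1mat[, l], a2mat[, l])
    copies <- copies[!is.na(copies)]
    list(p = table(copies) / length(copies), n = length(copies))
  })
  fij <- matrix(NA_real_, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      num <- 0; den <- 0
      for (l in seq_len(L)) {
        if (is.na(a1mat[i, l]) || is.na(a1mat[j, l])) next
        p <- freqs[[l]]$p; nl <- freqs[[l]]$n
        for (al in names(p)) {
          xi <- (sum(a1mat[i, l] == as.integer(al)) +
                 sum(a2mat[i, l] == as.integer(al))) / 2
          xj <- (sum(a1mat[j, l] == as.integer(al)) +
                 sum(a2mat[j, l] == as.integer(al))) / 2
          pa <- as.numeric(p[al])
          num <- num + (xi - pa) * (xj - pa) + pa * (1 - pa) / (nl - 1)
          den <- den + pa * (1 - pa)
        }
      }
      fij[i, j] <- fij[j, i] <- num / den
    }
  }
  fij
}

# identity disequilibrium g2 by direct loops over locus pairs/individuals
bf_g2 <- function(h) {
  L <- ncol(h)
  num <- den <- 0
  for (k in seq_len(L - 1)) {
    for (l in (k + 1):L) {
      both <- which(!is.na(h[, k]) & !is.na(h[, l]))
      n_kl <- length(both)
      if (n_kl < 2) next
      s_kl <- 0
      for (i in both) s_kl <- s_kl + h[i, k] * h[i, l]
      cross <- 0
      for (i in both) for (j in both)
        if (i != j) cross <- cross + h[i, k] * h[j, l]
      num <- num + n_kl * (s_kl / n_kl)
      den <- den + n_kl * (cross / (n_kl * (n_kl - 1)))
    }
  }
  num / den - 1
}
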