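# Method-of-moments variance components for gene-copy values in a nested
# design: copies within individuals within groups. Each typed individual
# contributes exactly two copies (diploid, both-or-neither missing).
#
# For y = allele indicator this is the Weir & Cockerham (1984) ANOVA whose
# ratio a/(a+b+c) is theta (FST) and b/(b+c) the within-group f (FIS); for
# y = allele size it yields the Slatkin-type RST (Michalakis & Excoffier
# form). Components are returned per call and must be summed over alleles
# and loci BEFORE taking ratios.
#
# y:     numeric vector of gene-copy values, length 2 * n_individuals
# group: group index per copy (integer or factor)
# Copies must be ordered so that copies 2i-1, 2i belong to individual i.
varcomp_copies <- function(y, group) {
  stopifnot(length(y) %% 2L == 0L)
  n_ind <- length(y) / 2L
  ind <- rep(seq_len(n_ind), each = 2L)
  group <- match(group, unique(group))
  gi <- group[2L * seq_len(n_ind)]  # group per individual
  K <- max(group)
  C <- length(y)
  ybar <- mean(y)
  yi <- (y[2L * seq_len(n_ind) - 1L] + y[2L * seq_len(n_ind)]) / 2
  cg <- tabulate(group, K)
  yg <- as.vector(rowsum(y, group, reorder = TRUE)) / cg
  ss_wi <- sum((y - rep(yi, each = 2L))^2)
  ss_ai <- sum(2 * (yi - yg[gi])^2)
  ms_wi <- ss_wi / n_ind
  sig_c <- ms_wi
  if (n_ind - K <= 0L)
    return(c(a = NA_real_, b = NA_real_, c = sig_c))
  ms_ai <- ss_ai / (n_ind - K)
  sig_b <- (ms_ai - sig_c) / 2
  if (K < 2L)
    return(c(a = NA_real_, b = sig_b, c = sig_c))
  ss_ag <- sum(cg * (yg - ybar)^2)
  ms_ag <- ss_ag / (K - 1L)
  k1 <- (C - sum(cg^2) / C) / (K - 1L)
  sig_a <- (ms_ag - sig_c - 2 * sig_b) / k1
  c(a = sig_a, b = sig_b, c = sig_c)
}

# Gene-copy values and per-copy groups for one locus, restricted to typed
# individuals of the selected groups. Returns NULL when any group has < 2
# typed individuals (no within-group df).
locus_copies <- function(table, l, group_of, groups) {
  a1 <- table$geno[, 2L * l - 1L]
  a2 <- table$geno[, 2L * l]
  keep <- !is.na(a1) & group_of %in% groups
  if (!any(keep)) return(NULL)
  g <- group_of[keep]
  if (any(table(factor(g, levels = groups)) < 2L)) return(NULL)
  y <- as.vector(rbind(a1[keep], a2[keep]))  # copies 2i-1, 2i per individual
  list(y = y, group = rep(g, each = 2L))
}
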