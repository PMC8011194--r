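#' Pairwise Loiselle kinship coefficients
#'
#' Multilocus ratio estimator of kinship between individuals i and j
#' relative to the reference allele frequencies: for each locus l and allele
#' a, the numerator term is
#' `(x_ila - p_la) * (x_jla - p_la) + p_la * (1 - p_la) / (n_l - 1)` and the
#' denominator term `p_la * (1 - p_la)`, where `x_ila` in {0, 0.5, 1} is i's
#' allele frequency, `p_la` the reference frequency and `n_l` the reference
#' gene-copy count. Terms are summed over alleles and over the loci typed in
#' both individuals before the ratio. Values can be negative; averaged over
#' all pairs of the reference sample the estimator is close to zero.
#'
#' @param table a [genotype_table()].
#' @param ref_group optional group label(s); reference allele frequencies
#'   are computed from those samples (default: all samples in `table`).
#' @return Object of class `kinship_matrix`: `ids`, `Fij` (symmetric matrix,
#'   `NA` diagonal and for pairs sharing no typed locus), per-locus numerator
#'   matrices (`num_locus`), per-locus denominator weights (`den_het`),
#'   per-locus typed indicators (`typed`), and `loci`. Per-locus pieces allow
#'   exact delete-one-locus jackknifing downstream.
#' @export
loiselle_kinship <- function(table, ref_group = NULL) {
  ref <- if (is.null(ref_group)) table
         else subset_samples(table, group = ref_group)
  fr <- allele_frequencies(ref)
  n <- n_samples(table)
  L <- n_loci(table)
  typed <- typed_matrix(table)
  num_locus <- vector("list", L)
  den_het <- numeric(L)
  a1 <- allele_matrix(table, 1L)
  a2 <- allele_matrix(table, 2L)
  for (l in seq_len(L)) {
    locus <- table$loci[l]
    li <- match(locus, fr$loci)
    if (is.na(li) || fr$n[li] < 2L) {
      num_locus[[l]] <- matrix(0, n, n)
      den_het[l] <- 0
      typed[, l] <- FALSE
      next
    }
    p <- fr$freq[[li]]
    alleles <- as.integer(names(p))
    nl <- fr$n[li]
    X <- (outer(a1[, l], alleles, "==") + outer(a2[, l], alleles, "==")) / 2
    X[!typed[, l], ] <- 0
    Xc <- sweep(X, 2L, p)
    Xc[!typed[, l], ] <- 0
    bias <- sum(p * (1 - p)) / (nl - 1)
    tt <- outer(typed[, l], typed[, l])
    num_locus[[l]] <- Xc %*% t(Xc) + bias * tt
    den_het[l] <- sum(p * (1 - p))
  }
  num <- Reduce(`+`, num_locus)
  den <- matrix(0, n, n)
  for (l in seq_len(L))
    den <- den + den_het[l] * outer(typed[, l], typed[, l])
  fij <- num / den
  fij[den == 0] <- NA_real_
  diag(fij) <- NA_real_
  dimnames(fij) <- list(table$samples$sample_id, table$samples$sample_id)
  structure(list(ids = table$samples$sample_id, Fij = fij,
                 num_locus = num_locus, den_het = den_het, typed = typed,
                 loci = table$loci, ref_n = fr$n),
            class = "kinship_matrix")
}

#' @export
print.kinship_matrix <- function(x, ...) {
  v <- x$Fij[upper.tri(x$Fij)]
  cat(sprintf(
    "kinship_matrix: %d individuals, %d loci; mean Fij = %.4f (range %.3f..%.3f)\n",
    length(x$ids), length(x$loci), mean(v, na.rm = TRUE),
    min(v, na.rm = TRUE), max(v, na.rm = TRUE)))
  invisible(x)
}

# Fij recomputed without locus l (delete-one jackknife building block)
kinship_drop_locus <- function(kin, l) {
  num <- Reduce(`+`, kin$num_locus[-l])
  n <- length(kin$ids)
  den <- matrix(0, n, n)
  for (m in seq_along(kin$loci)[-l])
    den <- den + kin$den_het[m] * outer(kin$typed[, m], kin$typed[, m])
  fij <- num / den
  fij[den == 0] <- NA_real_
  diag(fij) <- NA_real_
  fij
}
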