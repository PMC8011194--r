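#' Identity disequilibrium g2
#'
#' Moment estimator of the standardized excess of two-locus double
#' heterozygosity (David et al.-style g2). With heterozygosity indicators
#' `h_il` (1 = heterozygous, 0 = homozygous, undefined when missing), each
#' unordered locus pair (k, l) contributes, over the individuals typed at
#' both loci, a numerator term `sum_i h_ik * h_il / n_kl` and an unbiased
#' independence baseline
#' `(sum_i h_ik * sum_j h_jl - sum_i h_ik * h_il) / (n_kl * (n_kl - 1))`
#' (cross-individual products, which removes the finite-sample bias of the
#' plug-in product of means). Locus pairs are weighted by `n_kl` and
#' `g2 = sum(num) / sum(baseline) - 1`. Positive g2 signals correlated
#' heterozygosity across loci, as produced by partial selfing.
#'
#' @param table a [genotype_table()].
#' @param group optional group label(s).
#' @return list with `g2`, `n_loci` (loci with variation used), `n_pairs`
#'   (locus pairs).
#' @export
identity_disequilibrium_g2 <- function(table, group = NULL) {
  if (!is.null(group)) table <- subset_samples(table, group = group)
  h <- heterozygosity_indicators(table)
  g2_from_h(h)
}

# n x L matrix: 1 het, 0 hom, NA missing
heterozygosity_indicators <- function(table) {
  a1 <- allele_matrix(table, 1L)
  a2 <- allele_matrix(table, 2L)
  h <- (a1 != a2) * 1
  colnames(h) <- table$loci
  h
}

g2_from_h <- function(h) {
  # keep loci with observed variation in h
  keep <- apply(h, 2L, function(v) {
    v <- v[!is.na(v)]
    length(v) >= 2L && stats::var(v) > 0
  })
  if (sum(keep) < 2L)
    stop("g2 undefined: fewer than 2 loci with heterozygosity variation")
  h <- h[, keep, drop = FALSE]
  L <- ncol(h)
  num <- 0; den <- 0
  for (k in seq_len(L - 1L)) {
    for (l in (k + 1L):L) {
      both <- !is.na(h[, k]) & !is.na(h[, l])
      n_kl <- sum(both)
      if (n_kl < 2L) next
      hk <- h[both, k]; hl <- h[both, l]
      s_kk <- sum(hk); s_ll <- sum(hl); s_kl <- sum(hk * hl)
      num <- num + n_kl * (s_kl / n_kl)
      den <- den + n_kl * ((s_kk * s_ll - s_kl) / (n_kl * (n_kl - 1)))
    }
  }
  if (den == 0) stop("g2 undefined: no double heterozygosity baseline")
  list(g2 = num / den - 1, n_loci = L, n_pairs = L * (L - 1) / 2)
}

#' Expected identity disequilibrium under partial selfing
#'
#' Mixed-mating equilibrium: an individual's number of consecutive selfed
#' ancestors T is geometric, `P(T = t) = (1 - s) * s^t`, and heterozygosity
#' at each locus is halved per selfed generation. Hence
#' `g2(s) = E[(1/4)^T] / E[(1/2)^T]^2 - 1
#'        = (1 - s/2)^2 / ((1 - s) * (1 - s/4)) - 1`.
#'
#' @param s selfing rate in `[0, 1)`.
#' @return expected g2.
#' @export
g2_expected <- function(s) {
  stopifnot(all(s >= 0), all(s < 1))
  (1 - s / 2)^2 / ((1 - s) * (1 - s / 4)) - 1
}

#' Selfing rate from identity disequilibrium
#'
#' Inverts [g2_expected()] by bracketed monotone root finding on `[0, 1)`.
#' Non-positive g2 maps to 0; g2 beyond the s -> 1 asymptote saturates at
#' `1 - eps` with a flag.
#'
#' @param g2 estimated identity disequilibrium.
#' @param eps saturation margin near s = 1.
#' @return list with `s_hat` and logical `saturated`.
#' @export
selfing_from_g2 <- function(g2, eps = 1e-6) {
  stopifnot(is.finite(g2))
  if (g2 <= 0) return(list(s_hat = 0, saturated = FALSE))
  hi <- 1 - eps
  if (g2 >= g2_expected(hi)) return(list(s_hat = hi, saturated = TRUE))
  root <- stats::uniroot(function(s) g2_expected(s) - g2,
                         lower = 0, upper = hi, tol = 1e-12)
  list(s_hat = root$root, saturated = FALSE)
}

#' Selfing rate with jackknife-over-loci standard error
#'
#' Point estimate from all loci; delete-one-locus replicates of the selfing
#' rate give the jackknife SE. The estimate is labelled non-significant when
#' 0 lies inside `s_hat +/- 1.96 * SE`.
#'
#' @param table a [genotype_table()] with at least 3 loci.
#' @param group optional group label(s).
#' @return Object of class `mating_system_estimate`: `group`, `g2`, `s_hat`,
#'   `SE`, `n_loci`, `significant`, `saturated`.
#' @export
selfing_with_jackknife <- function(table, group = NULL) {
  if (!is.null(group)) table <- subset_samples(table, group = group)
  if (n_loci(table) < 3L) stop("need at least 3 loci for the jackknife")
  h <- heterozygosity_indicators(table)
  full <- g2_from_h(h)
  est <- selfing_from_g2(full$g2)
  reps <- vapply(seq_len(ncol(h)), function(l) {
    r <- tryCatch(g2_from_h(h[, -l, drop = FALSE]),
                  error = function(e) NULL)
    if (is.null(r)) NA_real_ else selfing_from_g2(r$g2)$s_hat
  }, numeric(1))
  reps <- reps[!is.na(reps)]
  L <- length(reps)
  se <- if (L >= 2L) sqrt((L - 1) / L * sum((reps - mean(reps))^2)) else NA_real_
  structure(list(group = if (is.null(group)) "ALL" else group,
                 g2 = full$g2, s_hat = est$s_hat, SE = se,
                 n_loci = full$n_loci,
                 significant = is.finite(se) &&
                   (est$s_hat - 1.96 * se > 0),
                 saturated = est$saturated),
            class = "mating_system_estimate")
}

#' @export
print.mating_system_estimate <- function(x, ...) {
  cat(sprintf(
    "mating_system_estimate [%s]: g2 = %.4f, s_hat = %.3f +/- %.3f (%d loci, %s)\n",
    paste(x$group, collapse = ","), x$g2, x$s_hat, x$SE, x$n_loci,
    if (x$significant) "significantly > 0" else "not significantly > 0"))
  invisible(x)
}
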