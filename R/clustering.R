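#' Maximum-likelihood genetic clustering by EM
#'
#' Fits a K-component mixture in which each cluster is a Hardy-Weinberg
#' population with its own allele frequencies and no admixture:
#' `P(genotype_i | k) = prod over typed loci of p_ka^2 (hom) or
#' 2 p_ka p_kb (het)`. The E-step computes posterior memberships
#' `q_ik proportional to pi_k P(genotype_i | k)`; the M-step re-estimates
#' cluster allele frequencies from q-weighted allele counts with a
#' pseudo-count of `1 / (2 n_l)` per allele (n_l = typed gene copies at
#' locus l) and the mixing proportions from mean memberships. The best of
#' `n_starts` seeded random initializations (Dirichlet fractional
#' memberships) is retained. Runs that empty a cluster are restarted.
#'
#' @param table a [genotype_table()].
#' @param K number of clusters (`1 <= K <= n/2`).
#' @param n_starts random restarts.
#' @param tol convergence tolerance on the log-likelihood.
#' @param max_iter maximum EM iterations per start.
#' @param seed RNG seed.
#' @return Object of class `cluster_assignment`: `K`, `q` (n x K posterior
#'   matrix), `hard` (argmax labels `1..K`), `freqs` (per-cluster allele
#'   frequencies), `mixing`, `logL`, `logL_trace` (best run), `AIC`,
#'   `n_parameters`, `ids`.
#' @export
em_cluster <- function(table, K, n_starts = 20L, tol = 1e-6,
                       max_iter = 500L, seed = 1L) {
  n <- n_samples(table)
  stopifnot(K >= 1L, K <= max(1L, n %/% 2L))
  enc <- encode_counts(table)
  n_par <- K * sum(enc$n_alleles - 1L) + (K - 1L)
  if (K == 1L) {
    fit <- em_single(enc, matrix(1, n, 1L), tol, max_iter)
    return(finish_cluster(fit, enc, table, 1L, n_par))
  }
  withr::with_seed(seed, {
    best <- NULL
    degenerate <- 0L
    for (s in seq_len(n_starts)) {
      fit <- NULL
      for (try in 1:5) {
        q0 <- matrix(stats::rgamma(n * K, 1), n, K)
        q0 <- q0 / rowSums(q0)
        fit <- em_single(enc, q0, tol, max_iter)
        if (!fit$degenerate) break
        fit <- NULL
      }
      if (is.null(fit)) { degenerate <- degenerate + 1L; next }
      if (is.null(best) || fit$logL > best$logL) best <- fit
    }
    if (is.null(best)) stop("all EM runs degenerate (empty cluster)")
    finish_cluster(best, enc, table, K, n_par)
  })
}

# allele-count encoding: n x sum(A_l) matrix of copy counts per allele,
# plus per-individual heterozygosity log(2) constant and locus block index
encode_counts <- function(table) {
  n <- n_samples(table)
  L <- n_loci(table)
  a1 <- allele_matrix(table, 1L)
  a2 <- allele_matrix(table, 2L)
  alleles <- lapply(seq_len(L), function(l)
    sort(unique(stats::na.omit(c(a1[, l], a2[, l])))))
  n_alleles <- lengths(alleles)
  block <- rep(seq_len(L), n_alleles)
  Atot <- sum(n_alleles)
  C <- matrix(0, n, Atot)
  off <- c(0L, cumsum(n_alleles))
  hetc <- numeric(n)
  n_copies <- integer(L)
  for (l in seq_len(L)) {
    typed <- !is.na(a1[, l])
    n_copies[l] <- 2L * sum(typed)
    i1 <- off[l] + match(a1[typed, l], alleles[[l]])
    i2 <- off[l] + match(a2[typed, l], alleles[[l]])
    w <- which(typed)
    C[cbind(w, i1)] <- C[cbind(w, i1)] + 1
    C[cbind(w, i2)] <- C[cbind(w, i2)] + 1
    hetc[w] <- hetc[w] + log(2) * (a1[w, l] != a2[w, l])
  }
  list(C = C, hetc = hetc, block = block, alleles = alleles,
       n_alleles = n_alleles, n_copies = n_copies, loci = table$loci)
}

em_single <- function(enc, q, tol, max_iter) {
  n <- nrow(q); K <- ncol(q)
  trace <- numeric(0)
  logL <- -Inf
  pseudo <- (1 / (2 * pmax(enc$n_copies, 1L)))[enc$block]
  for (it in seq_len(max_iter)) {
    # M-step from current memberships
    cs <- colSums(q)
    if (any(cs < 1e-9)) return(list(degenerate = TRUE))
    mixing <- cs / n
    wc <- t(enc$C) %*% q + pseudo          # Atot x K
    p <- apply(wc, 2L, function(col)
      unlist(lapply(split(col, enc$block), function(v) v / sum(v))))
    # E-step
    logp <- log(p)
    ll_ik <- enc$C %*% logp + enc$hetc + rep(log(mixing), each = n)
    m <- apply(ll_ik, 1L, max)
    q <- exp(ll_ik - m)
    q <- q / rowSums(q)
    logL_new <- sum(m + log(rowSums(exp(ll_ik - m))))
    trace <- c(trace, logL_new)
    if (is.finite(logL) && abs(logL_new - logL) < tol) {
      logL <- logL_new
      break
    }
    logL <- logL_new
  }
  if (K > 1L && any(colSums(q) / n < 1e-6))
    return(list(degenerate = TRUE))
  list(degenerate = FALSE, q = q, p = p, mixing = mixing, logL = logL,
       trace = trace)
}

finish_cluster <- function(fit, enc, table, K, n_par) {
  q <- fit$q
  hard <- max.col(q, ties.method = "first")
  freqs <- lapply(seq_len(K), function(k) {
    stats::setNames(
      lapply(seq_along(enc$alleles), function(l)
        stats::setNames(fit$p[enc$block == l, k], enc$alleles[[l]])),
      enc$loci)
  })
  structure(list(K = K, q = q, hard = hard, freqs = freqs,
                 mixing = fit$mixing, logL = fit$logL,
                 logL_trace = fit$trace,
                 AIC = -2 * fit$logL + 2 * n_par, n_parameters = n_par,
                 ids = table$samples$sample_id),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("cluster_assignment: K = %d, logL = %.2f, AIC = %.2f\n",
              x$K, x$logL, x$AIC))
  cat("  hard sizes:", paste(tabulate(x$hard, x$K), collapse = ", "), "\n")
  invisible(x)
}

#' Choose the number of clusters by information criterion
#'
#' Runs [em_cluster()] for `K = 1..k_max` and picks the K minimizing AIC,
#' ties broken toward smaller K.
#'
#' @inheritParams em_cluster
#' @param k_max largest K to consider.
#' @return list with `K` (chosen), `scores` (data.frame of K, logL, AIC),
#'   `fits` (list of `cluster_assignment`s).
#' @export
select_k <- function(table, k_max = 10L, n_starts = 20L, tol = 1e-6,
                     max_iter = 500L, seed = 1L) {
  stopifnot(k_max >= 1L)
  ks <- seq_len(min(k_max, max(1L, n_samples(table) %/% 2L)))
  fits <- lapply(ks, function(k)
    em_cluster(table, k, n_starts = n_starts, tol = tol,
               max_iter = max_iter, seed = seed + k))
  scores <- data.frame(K = ks,
                       logL = vapply(fits, `[[`, numeric(1), "logL"),
                       AIC = vapply(fits, `[[`, numeric(1), "AIC"))
  chosen <- ks[which.min(scores$AIC)]  # which.min takes the first = smallest K
  list(K = chosen, scores = scores, fits = fits)
}

#' Assign samples to clusters with an admixture threshold
#'
#' Samples whose maximum posterior membership reaches `threshold` get their
#' hard cluster label as group; the rest are marked unassigned and excluded
#' from per-cluster statistics.
#'
#' @param assignment a [em_cluster()] result.
#' @param table the [genotype_table()] the assignment was computed from.
#' @param threshold minimum posterior membership q for assignment.
#' @return list with `table` (grouped `genotype_table`, groups
#'   `cluster1..K`, unassigned samples dropped), `unassigned` (sample ids),
#'   `groups` (per-sample label incl. `NA` for unassigned, full order).
#' @export
apply_admixture_threshold <- function(assignment, table, threshold = 0.8) {
  stopifnot(identical(assignment$ids, table$samples$sample_id))
  maxq <- apply(assignment$q, 1L, max)
  lab <- ifelse(maxq >= threshold,
                sprintf("cluster%d", assignment$hard), NA_character_)
  keep <- which(!is.na(lab))
  tab <- table
  tab$samples$group <- lab
  list(table = subset_samples(tab, keep),
       unassigned = table$samples$sample_id[is.na(lab)],
       groups = lab)
}
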