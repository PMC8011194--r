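#' Logarithmically spaced distance class bounds
#'
#' Upper bounds of distance classes: the first bound is `first` meters (the
#' near-neighbour scale), subsequent bounds are log-spaced up to the maximum
#' observed distance.
#'
#' @param dist distance matrix (meters).
#' @param n_classes total number of classes.
#' @param first upper bound of the first class, meters.
#' @return Numeric vector of strictly increasing upper bounds.
#' @export
distance_classes <- function(dist, n_classes = 10L, first = 100) {
  dmax <- max(dist)
  if (dmax <= first) return(dmax)
  c(first, exp(seq(log(first), log(dmax), length.out = n_classes))[-1L])
}

#' Kinship-distance analysis: curve, slope, Sp and permutation test
#'
#' Quantifies fine-scale spatial genetic structure from a kinship matrix and
#' a matching distance matrix: (i) mean kinship per distance class (the
#' curve); (ii) the OLS regression slope `b_log` of pairwise Fij on
#' ln(distance) over all pairs (optionally restricted to a distance range);
#' (iii) the `Sp` statistic `-b_log / (1 - F1)` with `F1` the mean kinship in
#' the first class; (iv) a location-permutation test of the slope (spatial
#' positions permuted among individuals, two-sided rank p-value with the +1
#' correction); (v) optionally a delete-one-locus jackknife SE for Sp.
#'
#' Pairs at zero distance are excluded from the log-distance regression but
#' included in `Fn` (mean kinship among pairs closer than `fn_radius`).
#'
#' @param kin a [loiselle_kinship()] result.
#' @param dist symmetric distance matrix in meters, same order as `kin`.
#' @param classes upper bounds of distance classes (default:
#'   [distance_classes()]).
#' @param n_perm location permutations (0 disables).
#' @param seed RNG seed for permutations.
#' @param jackknife compute the delete-one-locus SE of Sp.
#' @param fn_radius neighbourhood radius in meters for `Fn`.
#' @param range optional `c(lo, hi)`: regression restricted to pairs with
#'   `lo < d <= hi`.
#' @param min_pairs_warn warn when a class holds fewer pairs than this.
#' @return Object of class `sgs_result`: `classes` (data.frame with bounds,
#'   mean distance, mean Fij, pair counts), `b_log`, `F1`, `Fn`, `Sp`,
#'   `Sp_SE`, `perm_p`, `n_perm`, `n_pairs`.
#' @export
kinship_distance_analysis <- function(kin, dist, classes = NULL,
                                      n_perm = 10000L, seed = 1L,
                                      jackknife = TRUE, fn_radius = 100,
                                      range = NULL, min_pairs_warn = 30L) {
  n <- length(kin$ids)
  stopifnot(nrow(dist) == n, ncol(dist) == n)
  ut <- upper.tri(dist)
  f <- kin$Fij[ut]
  d <- dist[ut]
  ok <- !is.na(f)
  if (is.null(classes)) classes <- distance_classes(dist[ut][ok])
  lower <- c(0, classes[-length(classes)])
  cls <- findInterval(d, classes, left.open = TRUE) + 1L
  cls[cls > length(classes)] <- length(classes)
  cl_df <- data.frame(
    class = seq_along(classes), lower_m = lower, upper_m = classes,
    mean_distance_m = as.vector(tapply(d[ok], factor(cls[ok],
                                levels = seq_along(classes)), mean)),
    mean_Fij = as.vector(tapply(f[ok], factor(cls[ok],
                                levels = seq_along(classes)), mean)),
    n_pairs = as.vector(table(factor(cls[ok], levels = seq_along(classes)))))
  if (sum(cl_df$n_pairs >= min_pairs_warn) < 2L)
    warning("fewer than 2 distance classes hold >= ", min_pairs_warn,
            " pairs; class means are unstable")
  in_range <- ok & d > 0
  if (!is.null(range)) in_range <- in_range & d > range[1] & d <= range[2]
  if (sum(in_range) < 2L || stats::var(log(d[in_range])) == 0)
    stop("log-distance regression undefined: all usable pairs at identical ",
         "distance")
  b <- ols_slope(log(d[in_range]), f[in_range])
  f1 <- cl_df$mean_Fij[1L]
  fn <- mean(f[ok & d < fn_radius])
  sp <- -b / (1 - f1)
  perm_p <- NA_real_
  if (n_perm > 0L) {
    perm_p <- withr::with_seed(seed, {
      bperm <- vapply(seq_len(n_perm), function(r) {
        prm <- sample.int(n)
        dp <- dist[prm, prm][ut]
        use <- !is.na(f) & dp > 0
        if (!is.null(range)) use <- use & dp > range[1] & dp <= range[2]
        if (sum(use) < 2L) return(NA_real_)
        ols_slope(log(dp[use]), f[use])
      }, numeric(1))
      bperm <- bperm[!is.na(bperm)]
      p_lo <- (sum(bperm <= b) + 1) / (length(bperm) + 1)
      p_up <- (sum(bperm >= b) + 1) / (length(bperm) + 1)
      min(1, 2 * min(p_lo, p_up))
    })
  }
  sp_se <- NA_real_
  if (jackknife && length(kin$loci) >= 2L) {
    sp_l <- vapply(seq_along(kin$loci), function(l) {
      fl <- kinship_drop_locus(kin, l)[ut]
      use <- in_range & !is.na(fl)
      bl <- ols_slope(log(d[use]), fl[use])
      f1l <- mean(fl[ok & !is.na(fl) & cls == 1L], na.rm = TRUE)
      -bl / (1 - f1l)
    }, numeric(1))
    L <- length(sp_l)
    sp_se <- sqrt((L - 1) / L * sum((sp_l - mean(sp_l))^2))
  }
  structure(list(classes = cl_df, b_log = b, F1 = f1, Fn = fn, Sp = sp,
                 Sp_SE = sp_se, perm_p = perm_p, n_perm = n_perm,
                 n_pairs = sum(ok), fn_radius = fn_radius, range = range),
            class = "sgs_result")
}

ols_slope <- function(x, y) {
  xc <- x - mean(x)
  sum(xc * y) / sum(xc^2)
}

#' @export
print.sgs_result <- function(x, ...) {
  cat(sprintf(
    "sgs_result: %d pairs; b_log = %.5f, F1 = %.4f, Fn(<%gm) = %.4f\n",
    x$n_pairs, x$b_log, x$F1, x$fn_radius, x$Fn))
  cat(sprintf("  Sp = %.5f%s%s\n", x$Sp,
              if (!is.na(x$Sp_SE)) sprintf(" +/- %.5f (jackknife SE)", x$Sp_SE)
              else "",
              if (!is.na(x$perm_p)) sprintf(", permutation p = %.4g", x$perm_p)
              else ""))
  invisible(x)
}
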