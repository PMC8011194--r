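#' Indirect gene-dispersal estimation under isolation by distance
#'
#' Iterative Wright-Malecot estimator: under isolation by distance, pairwise
#' kinship decays approximately linearly with ln(distance) at rate
#' `(Fn - 1) / (4 * pi * De * sigma_g^2)`, where `sigma_g^2` is half the
#' mean squared parent-offspring distance, `De` the effective density of
#' adults (fixed input), and `Fn` the mean kinship between neighbours (pairs
#' closer than `fn_radius`). The approximation holds for distances between
#' `sigma_g` and roughly `0.56 * sigma_g / sqrt(2 * mu)`, so the regression
#' is restricted to `(sigma_g, range_factor * sigma_g]` and `sigma_g` is
#' solved iteratively:
#' slope `b` over the restricted range, `Nb = (1 - Fn) / (-b)`,
#' `sigma_g = sqrt(Nb / (4 * pi * De))`, repeat until relative change is
#' below `tol`.
#'
#' The initial `sigma_g` comes from the slope over the full distance range.
#' Non-convergence (max iterations, non-negative slope, or a restricted
#' range holding fewer than `min_pairs` pairs) is reported via
#' `converged = FALSE`, never as an error. When the restricted range holds
#' too few pairs at initialization, the smallest window with at least
#' `min_pairs` pairs is used instead and flagged.
#'
#' @param kin a [loiselle_kinship()] result.
#' @param dist matching distance matrix in meters.
#' @param De effective density of adults per square meter.
#' @param range_factor upper regression bound as a multiple of `sigma_g`
#'   (the conventional choices are 20 or 100).
#' @param tol relative convergence tolerance on `sigma_g`.
#' @param max_iter maximum iterations.
#' @param fn_radius neighbourhood radius in meters for `Fn`.
#' @param min_pairs minimum pairs required in the restricted range.
#' @param max_distance hard upper cap (meters) on the regression window,
#'   `Inf` by default. The Wright-Malecot log-linear decay assumes an
#'   effectively unbounded habitat; when the sampled area is bounded (or
#'   periodic, as in the bundled torus simulator) the kinship curve is
#'   forced flat near the maximum observable distance, which biases the
#'   slope toward zero. Cap the window at roughly half the habitat extent
#'   in such designs.
#' @param mu optional mutation rate; when supplied, a warning is issued if
#'   the regression window exceeds the validity bound
#'   `0.56 * sigma_g / sqrt(2 * mu)`.
#' @return Object of class `dispersal_estimate`: `sigma_g` (meters), `Nb`
#'   (neighbourhood size, `4 * pi * De * sigma_g^2` at convergence), `De`,
#'   `Fn`, `b` (final slope), `range_factor`, `iterations`, `converged`,
#'   `flags`.
#' @export
estimate_sigma_g <- function(kin, dist, De, range_factor = 20, tol = 1e-3,
                             max_iter = 100L, fn_radius = 100,
                             min_pairs = 30L, max_distance = Inf,
                             mu = NULL) {
  stopifnot(De > 0, range_factor > 1, max_distance > 0)
  ut <- upper.tri(dist)
  f <- kin$Fij[ut]
  d <- dist[ut]
  ok <- !is.na(f)
  near <- ok & d < fn_radius
  if (!any(near))
    stop("Fn not computable: no pair closer than ", fn_radius, " m")
  fn <- mean(f[near])
  flags <- character(0)
  fail <- function(why, sg = NA_real_, nb = NA_real_, b = NA_real_, it = 0L)
    structure(list(sigma_g = sg, Nb = nb, De = De, Fn = fn, b = b,
                   range_factor = range_factor, iterations = it,
                   converged = FALSE, flags = c(flags, why)),
              class = "dispersal_estimate")
  upper <- function(sg) min(range_factor * sg, max_distance)
  # initial sigma from the full-range slope (within the distance cap)
  use <- ok & d > 0 & d <= max_distance
  b <- ols_slope(log(d[use]), f[use])
  if (b >= 0) return(fail("non-negative full-range slope"))
  sg <- sqrt((1 - fn) / (-b) / (4 * pi * De))
  if (sg > max_distance / 4) {
    # leave the initial window at least a factor 4 wide; the damped
    # fixed-point search then approaches the solution from below
    sg <- max_distance / 4
    flags <- c(flags, "initial sigma clamped to max_distance/4")
  }
  if (sum(ok & d > sg & d <= upper(sg)) < min_pairs) {
    # fall back to the smallest window holding min_pairs pairs
    dpos <- sort(d[ok & d > 0])
    if (length(dpos) < min_pairs) return(fail("fewer than min_pairs pairs"))
    sg <- dpos[min_pairs] / range_factor
    flags <- c(flags, "initial window widened to reach min_pairs")
  }
  # Damped fixed-point iteration (geometric mean of old and proposed
  # sigma). The window -> slope map is piecewise constant in sigma, so the
  # raw update can cycle between windows; revisiting an earlier sigma within
  # tol is treated as convergence at the cycle mean.
  it <- 0L
  hist_sg <- sg
  repeat {
    it <- it + 1L
    use <- ok & d > sg & d <= upper(sg)
    if (sum(use) < min_pairs)
      return(fail("restricted range holds too few pairs", it = it))
    b <- ols_slope(log(d[use]), f[use])
    if (b >= 0)
      return(fail("non-negative restricted-range slope", it = it))
    st <- dispersal_step(b, fn, De)
    nb <- st$Nb
    sg_new <- sqrt(sg * st$sigma_g)
    if (abs(sg_new - sg) / sg < tol) {
      sg <- sg_new
      break
    }
    back <- which(abs(sg_new - hist_sg) / sg_new < tol)
    if (length(back) > 0L) {
      sg <- mean(c(hist_sg[back[1L]:length(hist_sg)], sg_new))
      flags <- c(flags, "converged on a cycle (cycle-averaged sigma)")
      break
    }
    hist_sg <- c(hist_sg, sg_new)
    sg <- sg_new
    if (it >= max_iter)
      return(fail("max iterations reached", sg, nb, b, it))
  }
  if (!is.null(mu)) {
    upper <- upper(sg)
    valid <- 0.56 * sg / sqrt(2 * mu)
    if (upper > valid)
      warning(sprintf(
        "regression window upper bound (%.0f m) exceeds the validity bound 0.56*sigma_g/sqrt(2*mu) = %.0f m",
        upper, valid))
  }
  structure(list(sigma_g = sg, Nb = 4 * pi * De * sg^2, De = De, Fn = fn,
                 b = b, range_factor = range_factor, iterations = it,
                 converged = TRUE, flags = flags),
            class = "dispersal_estimate")
}

#' @export
print.dispersal_estimate <- function(x, ...) {
  if (x$converged)
    cat(sprintf(
      "dispersal_estimate: sigma_g = %.1f m, Nb = %.1f (De = %g /m^2, range sigma_g..%dsigma_g, %d iterations)\n",
      x$sigma_g, x$Nb, x$De, x$range_factor, x$iterations))
  else
    cat("dispersal_estimate: NOT converged (", paste(x$flags, collapse = "; "),
        ")\n", sep = "")
  invisible(x)
}

#' One Wright-Malecot update step
#'
#' Given a regression slope `b < 0` of kinship on ln(distance), the
#' neighbourhood kinship `Fn` and a fixed effective density `De` (per m^2),
#' returns the neighbourhood size `Nb = (1 - Fn) / (-b)` and the implied
#' gene dispersal distance `sigma_g = sqrt(Nb / (4 * pi * De))`. This is the
#' closed-form step iterated by [estimate_sigma_g()].
#'
#' @param b slope of pairwise kinship on ln(distance); must be negative.
#' @param Fn mean kinship among near neighbours.
#' @param De effective density, adults per square meter.
#' @return list with `Nb` and `sigma_g` (meters).
#' @export
dispersal_step <- function(b, Fn, De) {
  stopifnot(b < 0, De > 0)
  nb <- (1 - Fn) / (-b)
  list(Nb = nb, sigma_g = sqrt(nb / (4 * pi * De)))
}

#' Effective-density scenarios
#'
#' Effective densities as fixed fractions of the census adult density, in
#' both per-hectare and per-square-meter units (1 ha = 10,000 m^2).
#'
#' @param D_per_ha census density of adults per hectare.
#' @param fractions fractions of `D` to consider (default 1/2, 1/4, 1/10).
#' @return data.frame with `fraction`, `De_per_ha`, `De_per_m2`.
#' @export
density_scenarios <- function(D_per_ha, fractions = c(1 / 2, 1 / 4, 1 / 10)) {
  stopifnot(D_per_ha > 0)
  data.frame(fraction = fractions,
             De_per_ha = fractions * D_per_ha,
             De_per_m2 = fractions * D_per_ha / 1e4)
}
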