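#' Parameters for the spatially explicit isolation-by-distance simulator
#'
#' Describes a forward-in-time, non-overlapping-generations population of
#' `N = density * side^2` diploid individuals on a square torus. Seed and
#' pollen movement are isotropic bivariate Gaussian kernels; microsatellite
#' loci mutate stepwise (+/- 1 repeat unit) with reflection at the allele
#' range bounds. The composite gene-dispersal parameter realized by this
#' model is `sigma_g = sqrt(sigma_s^2 + sigma_p^2 / 2)` (pollen moves only
#' the paternal gamete).
#'
#' @param side torus side length in meters.
#' @param density adults per square meter (`density * side^2 >= 50`).
#' @param selfing selfing rate in `[0, 1)`.
#' @param sigma_s seed dispersal kernel SD, meters.
#' @param sigma_p pollen dispersal kernel SD, meters.
#' @param loci number of unlinked microsatellite loci.
#' @param mu stepwise mutation rate per locus per generation, in `[0, 0.01]`.
#' @param allele_range integer vector `c(min, max)` of allele states
#'   (repeat units); mutations reflect at the bounds.
#' @param generations number of non-overlapping generations to run.
#' @param seed RNG seed.
#' @return A validated list of class `ibd_params`.
#' @export
ibd_params <- function(side = 1000, density = 0.002, selfing = 0,
                       sigma_s = 50, sigma_p = 200, loci = 10L,
                       mu = 1e-3, allele_range = c(10L, 59L),
                       generations = 500L, seed = 1L) {
  stopifnot(side > 0, density > 0, selfing >= 0, selfing < 1,
            sigma_s > 0, sigma_p > 0, loci >= 1, mu >= 0, mu <= 0.01,
            length(allele_range) == 2L, allele_range[1] >= 1,
            allele_range[2] > allele_range[1], generations >= 1)
  n <- round(density * side^2)
  if (n < 50) stop("density * side^2 must be >= 50 individuals, got ", n)
  if (sigma_s >= side / 4 || sigma_p >= side / 4)
    warning("dispersal kernel SD >= side/4: the torus is effectively ",
            "panmictic and sigma_g loses meaning")
  structure(list(side = side, density = density, selfing = selfing,
                 sigma_s = sigma_s, sigma_p = sigma_p, loci = as.integer(loci),
                 mu = mu, allele_range = as.integer(allele_range),
                 generations = as.integer(generations), n = as.integer(n),
                 seed = as.integer(seed)),
            class = "ibd_params")
}

# shortest signed displacement a - b on a circle of circumference side
torus_diff <- function(a, b, side) {
  d <- (a - b) %% side
  d - side * (d > side / 2)
}

torus_dist2 <- function(x1, y1, x2, y2, side) {
  torus_diff(x1, x2, side)^2 + torus_diff(y1, y2, side)^2
}

#' Forward simulation of genotypes under isolation by distance
#'
#' Runs the model described in [ibd_params()]: each generation, every
#' offspring draws a mother uniformly at random; with probability `selfing`
#' the father is the mother, otherwise a father is drawn with probability
#' proportional to a bivariate Gaussian of SD `sigma_p` in toroidal distance
#' from the mother (exact kernel, by rejection sampling with a weighted
#' fallback). The offspring settles at the mother's position plus a Gaussian
#' displacement of SD `sigma_s` (wrapped). Each transmitted allele mutates
#' +/- 1 repeat unit with probability `mu`, reflecting at the range bounds.
#'
#' The realized gene dispersal is tracked over the last `track_generations`
#' generations as `sqrt(mean(parent-offspring squared gene distance) / 2)`,
#' which should match `sigma_g_true` — the internal consistency check that
#' the returned truth label is correct.
#'
#' @param params an [ibd_params()] object.
#' @param sample_n optionally subsample this many individuals from the final
#'   generation (uniform, seeded).
#' @param track_generations how many final generations enter the realized
#'   dispersal estimate.
#' @param keep_parents if `TRUE`, also return the parental generation and the
#'   mother/father index of every final-generation offspring.
#' @return list of class `ibd_sim`: `table` (planar [genotype_table()]),
#'   `sigma_g_true`, `sigma_g_realized`, `params`, and if `keep_parents` the
#'   elements `parents` (a `genotype_table`), `mother`, `father` (indices
#'   into `parents`) restricted to the *full* final generation before
#'   subsampling, plus `sample_index`.
#' @export
simulate_ibd <- function(params, sample_n = NULL, track_generations = 10L,
                         keep_parents = FALSE) {
  stopifnot(inherits(params, "ibd_params"))
  p <- params
  out <- withr::with_seed(p$seed,
                          simulate_ibd_impl(p, sample_n, track_generations,
                                            keep_parents))
  out
}

simulate_ibd_impl <- function(p, sample_n, track_generations, keep_parents) {
  n <- p$n; L <- p$side; nl <- p$loci
  amin <- p$allele_range[1]; amax <- p$allele_range[2]
  x <- stats::runif(n, 0, L)
  y <- stats::runif(n, 0, L)
  # alleles: n x 2*loci, maximal standing diversity at start
  geno <- matrix(sample(amin:amax, n * 2L * nl, replace = TRUE), n, 2L * nl)
  disp2 <- numeric(0)  # squared parent-offspring gene distances (tracked)
  track_from <- p$generations - track_generations + 1L
  for (gen in seq_len(p$generations)) {
    mothers <- sample.int(n, n, replace = TRUE)
    self <- stats::runif(n) < p$selfing
    fathers <- draw_fathers(x, y, mothers, self, p$sigma_p, L)
    # gametes: one allele per parent per locus, independent segregation
    pick_m <- matrix(sample.int(2L, n * nl, replace = TRUE), n, nl)
    pick_f <- matrix(sample.int(2L, n * nl, replace = TRUE), n, nl)
    col_m <- 2L * (col(pick_m)) - (2L - pick_m)
    col_f <- 2L * (col(pick_f)) - (2L - pick_f)
    gam_m <- matrix(geno[cbind(rep(mothers, nl), as.vector(col_m))], n, nl)
    gam_f <- matrix(geno[cbind(rep(fathers, nl), as.vector(col_f))], n, nl)
    if (p$mu > 0) {
      gam_m <- mutate_smm(gam_m, p$mu, amin, amax)
      gam_f <- mutate_smm(gam_f, p$mu, amin, amax)
    }
    newgeno <- matrix(NA_integer_, n, 2L * nl)
    newgeno[, 2L * seq_len(nl) - 1L] <- gam_m
    newgeno[, 2L * seq_len(nl)] <- gam_f
    nx <- (x[mothers] + stats::rnorm(n, 0, p$sigma_s)) %% L
    ny <- (y[mothers] + stats::rnorm(n, 0, p$sigma_s)) %% L
    if (gen >= track_from) {
      d2m <- torus_dist2(nx, ny, x[mothers], y[mothers], L)
      d2f <- torus_dist2(nx, ny, x[fathers], y[fathers], L)
      disp2 <- c(disp2, d2m, d2f)
    }
    if (gen == p$generations && keep_parents) {
      parents <- list(x = x, y = y, geno = geno,
                      mother = mothers, father = fathers)
    }
    geno <- newgeno
    x <- nx; y <- ny
  }
  sigma_real <- sqrt(mean(disp2) / 2)
  ids <- sprintf("ind%04d", seq_len(n))
  mk_table <- function(ix, xx, yy, gg, pre = "ind") {
    genotype_table(data.frame(sample_id = sprintf("%s%04d", pre, ix),
                              x = xx[ix], y = yy[ix], group = NA_character_,
                              stringsAsFactors = FALSE),
                   gg[ix, , drop = FALSE],
                   sprintf("loc%02d", seq_len(nl)), "planar")
  }
  keep <- if (is.null(sample_n)) seq_len(n)
          else sort(sample.int(n, min(sample_n, n)))
  res <- list(table = mk_table(keep, x, y, geno),
              sigma_g_true = sqrt(p$sigma_s^2 + p$sigma_p^2 / 2),
              sigma_g_realized = sigma_real,
              sample_index = keep, params = p)
  if (keep_parents) {
    res$parents <- mk_table(seq_len(n), parents$x, parents$y, parents$geno,
                            pre = "par")
    res$mother <- parents$mother
    res$father <- parents$father
  }
  class(res) <- "ibd_sim"
  res
}

# Fathers for non-selfed offspring: exact Gaussian kernel in toroidal
# distance from the mother. Vectorized rejection sampling against uniform
# proposals; stragglers (tiny kernels) fall back to an exact weighted draw
# via the Gumbel-max trick on the full weight matrix.
draw_fathers <- function(x, y, mothers, self, sigma_p, side,
                         max_rounds = 50L) {
  n <- length(mothers)
  fathers <- integer(n)
  fathers[self] <- mothers[self]
  pending <- which(!self)
  two_s2 <- 2 * sigma_p^2
  rounds <- 0L
  while (length(pending) > 0L && rounds < max_rounds) {
    cand <- sample.int(n, length(pending), replace = TRUE)
    m <- mothers[pending]
    d2 <- torus_dist2(x[cand], y[cand], x[m], y[m], side)
    acc <- cand != m & stats::runif(length(pending)) < exp(-d2 / two_s2)
    fathers[pending[acc]] <- cand[acc]
    pending <- pending[!acc]
    rounds <- rounds + 1L
  }
  if (length(pending) > 0L) {
    m <- mothers[pending]
    logw <- -outer(seq_along(pending), seq_len(n),
                   function(i, j) torus_dist2(x[m[i]], y[m[i]],
                                              x[j], y[j], side)) / two_s2
    logw[cbind(seq_along(pending), m)] <- -Inf  # no implicit selfing
    g <- -log(-log(matrix(stats::runif(length(logw)), nrow(logw))))
    fathers[pending] <- max.col(logw + g, ties.method = "first")
  }
  fathers
}

# stepwise mutation: +/- 1 repeat unit with probability mu, reflected
mutate_smm <- function(al, mu, amin, amax) {
  hit <- which(stats::runif(length(al)) < mu)
  if (length(hit) == 0L) return(al)
  step <- ifelse(stats::runif(length(hit)) < 0.5, -1L, 1L)
  v <- al[hit] + step
  v[v > amax] <- amax - 1L
  v[v < amin] <- amin + 1L
  al[hit] <- v
  al
}

#' Parameters for the island/deme genotype generator
#'
#' Demes drift independently from a common ancestral allele-frequency
#' distribution under the Balding-Nichols construction: ancestral
#' frequencies are symmetric-Dirichlet per locus, deme frequencies are
#' Dirichlet with concentration `ancestral * (1 - F) / F`, and individuals
#' are drawn in Hardy-Weinberg proportions within demes. `F` is therefore
#' the target (expected) differentiation between demes.
#'
#' @param k number of demes.
#' @param f drift parameter / target FST, in (0, 1).
#' @param n_alleles ancestral alleles per locus.
#' @param n_per_deme diploid individuals sampled per deme.
#' @param loci number of loci.
#' @param allele_base smallest allele state (consecutive repeat units).
#' @param seed RNG seed.
#' @return A validated list of class `deme_params`.
#' @export
deme_params <- function(k = 2L, f = 0.2, n_alleles = 5L, n_per_deme = 100L,
                        loci = 10L, allele_base = 10L, seed = 1L) {
  stopifnot(k >= 1, f > 0, f < 1, n_alleles >= 2, n_per_deme >= 1, loci >= 1)
  structure(list(k = as.integer(k), f = f, n_alleles = as.integer(n_alleles),
                 n_per_deme = as.integer(n_per_deme), loci = as.integer(loci),
                 allele_base = as.integer(allele_base),
                 seed = as.integer(seed)),
            class = "deme_params")
}

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) g[which.max(alpha)] <- 1
  g / sum(g)
}

#' Simulate genotypes from drifted demes (Balding-Nichols)
#'
#' @param params a [deme_params()] object.
#' @return A planar [genotype_table()] whose `group` column is the true deme
#'   label (`deme1`, `deme2`, ...). Deme centers are laid out 10 km apart
#'   with 100 m within-deme scatter, and the ancestral frequency draw is
#'   attached as attribute `ancestral`.
#' @export
simulate_demes <- function(params) {
  stopifnot(inherits(params, "deme_params"))
  p <- params
  withr::with_seed(p$seed, {
    anc <- replicate(p$loci, rdirichlet1(rep(1, p$n_alleles)),
                     simplify = FALSE)
    n <- p$k * p$n_per_deme
    geno <- matrix(NA_integer_, n, 2L * p$loci)
    sizes <- p$allele_base + seq_len(p$n_alleles) - 1L
    for (d in seq_len(p$k)) {
      rows <- (d - 1L) * p$n_per_deme + seq_len(p$n_per_deme)
      for (l in seq_len(p$loci)) {
        pf <- if (p$k == 1L) anc[[l]]
              else rdirichlet1(anc[[l]] * (1 - p$f) / p$f)
        copies <- sample(sizes, 2L * p$n_per_deme, replace = TRUE, prob = pf)
        geno[rows, 2L * l - 1L] <- copies[seq_len(p$n_per_deme)]
        geno[rows, 2L * l] <- copies[p$n_per_deme + seq_len(p$n_per_deme)]
      }
    }
    deme <- rep(sprintf("deme%d", seq_len(p$k)), each = p$n_per_deme)
    cx <- rep((seq_len(p$k) - 1L) * 10000, each = p$n_per_deme)
    samples <- data.frame(
      sample_id = sprintf("s%04d", seq_len(n)),
      x = cx + stats::rnorm(n, 0, 100),
      y = stats::rnorm(n, 0, 100),
      group = deme, stringsAsFactors = FALSE)
    tab <- genotype_table(samples, geno,
                          sprintf("loc%02d", seq_len(p$loci)), "planar")
    attr(tab, "ancestral") <- anc
    tab
  })
}

#' Randomly delete genotypes
#'
#' Sets each (sample, locus) genotype missing independently with probability
#' `rate`; emulates real-data missingness for robustness tests.
#'
#' @param table a [genotype_table()].
#' @param rate missingness probability in `[0, 1)`.
#' @param seed RNG seed.
#' @return A `genotype_table` with injected missing genotypes.
#' @export
inject_missingness <- function(table, rate, seed) {
  stopifnot(rate >= 0, rate < 1)
  if (rate == 0) return(table)
  L <- n_loci(table)
  withr::with_seed(seed, {
    hit <- matrix(stats::runif(n_samples(table) * L) < rate,
                  n_samples(table), L)
    g <- table$geno
    g[, 2L * seq_len(L) - 1L][hit] <- NA_integer_
    g[, 2L * seq_len(L)][hit] <- NA_integer_
    genotype_table(table$samples, g, table$loci, table$coord_system)
  })
}
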