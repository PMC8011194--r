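#' Pairwise geographic distances in meters
#'
#' Planar coordinates give Euclidean distances; geographic coordinates
#' (decimal degrees, x = longitude, y = latitude) give great-circle
#' (haversine) distances on a sphere of radius 6,371,000 m.
#'
#' @param table a [genotype_table()].
#' @return Symmetric numeric matrix of distances in meters, zero diagonal,
#'   dimnames = sample ids.
#' @export
pairwise_distances <- function(table) {
  x <- table$samples$x
  y <- table$samples$y
  if (anyNA(x) || anyNA(y))
    stop("missing coordinate for sample(s): ",
         paste(table$samples$sample_id[is.na(x) | is.na(y)], collapse = ", "))
  if (table$coord_system == "planar") {
    d <- as.matrix(stats::dist(cbind(x, y)))
  } else {
    d <- haversine_matrix(x, y)
  }
  dimnames(d) <- list(table$samples$sample_id, table$samples$sample_id)
  d
}

EARTH_RADIUS_M <- 6371000

haversine_matrix <- function(lon, lat, radius = EARTH_RADIUS_M) {
  phi <- lat * pi / 180
  lam <- lon * pi / 180
  n <- length(phi)
  dphi <- outer(phi, phi, "-") / 2
  dlam <- outer(lam, lam, "-") / 2
  a <- sin(dphi)^2 + (cos(phi) %o% cos(phi)) * sin(dlam)^2
  a[a > 1] <- 1
  d <- 2 * radius * asin(sqrt(a))
  diag(d) <- 0
  d
}
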