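#' Build the three-patch landscape
#'
#' Three circular patches of equal radius sit at the vertices of an
#' equilateral triangle, pairwise equidistant with `edge_gap` units between
#' patch edges (so centers are `edge_gap + 2 * radius` apart). Each patch has
#' its own rate of resource-quality change; the landscape *heterogeneity* is
#' the number of unique rates (1, 2 or 3). All patches start at the same
#' resource quality.
#'
#' @param radius patch radius in landscape units (default 10).
#' @param edge_gap edge-to-edge spacing between patches (default 50).
#' @param rates numeric vector of exactly 3 per-patch rates of
#'   resource-quality change (trait units per generation).
#' @param env_max trait-range maximum shared by phenotype and resource
#'   quality (default 140).
#' @param env_init initial resource quality of every patch (default 70).
#' @param K per-patch carrying capacity (default 200).
#' @return an object of class `nc_landscape`: list with `centers` (3 x 2
#'   matrix), `radius`, `edge_gap`, `rates`, `K`, `env_max`, `quality`
#'   (current per-patch quality), `heterogeneity`.
#' @export
#' @examples
#' build_landscape(rates = c(1e-3, 2.5e-4, 1e-4))
build_landscape <- function(radius = 10, edge_gap = 50,
                            rates = c(1e-3, 2.5e-4, 1e-4),
                            env_max = 140, env_init = 70, K = 200) {
  if (radius <= 0) stop("`radius` must be positive")
  if (edge_gap < 0) stop("`edge_gap` must be non-negative")
  if (length(rates) != 3L) stop("exactly 3 patch rates are required")
  if (K <= 0) stop("`K` must be positive")
  side <- edge_gap + 2 * radius
  # equilateral triangle, centroid at the origin
  rad <- side / sqrt(3)
  ang <- pi / 2 + 2 * pi * (0:2) / 3
  centers <- cbind(x = rad * cos(ang), y = rad * sin(ang))
  structure(
    list(centers = centers, radius = radius, edge_gap = edge_gap,
         rates = as.numeric(rates), K = K, env_max = env_max,
         quality = rep(env_init, 3L),
         heterogeneity = length(unique(rates))),
    class = "nc_landscape")
}

#' @export
print.nc_landscape <- function(x, ...) {
  cat(sprintf(
    "<nc_landscape> 3 patches, radius %g, edge gap %g (centers %g apart)\n",
    x$radius, x$edge_gap, x$edge_gap + 2 * x$radius))
  cat(sprintf("  rates: %s (heterogeneity %d); quality: %s; K = %g\n",
              paste(signif(x$rates, 3), collapse = ", "), x$heterogeneity,
              paste(signif(x$quality, 4), collapse = ", "), x$K))
  invisible(x)
}

#' Locate the patch containing a point
#'
#' Patches are closed discs; because they do not overlap the containing patch
#' is unique.
#'
#' @param point numeric length-2 coordinates `(x, y)`.
#' @param landscape an `nc_landscape`.
#' @return the patch index (1-3), or `NA_integer_` if the point lies in the
#'   matrix between patches.
#' @export
locate_patch <- function(point, landscape) {
  d2 <- (landscape$centers[, 1] - point[1])^2 +
        (landscape$centers[, 2] - point[2])^2
  hit <- which(d2 <= landscape$radius^2)
  if (length(hit)) hit[1L] else NA_integer_
}

# Vectorized passive dispersal for a cohort.
# Each individual leaves with probability d[j]; a mover starts from a
# uniform-random point inside its source patch and travels at a uniform
# angle for a uniform 0-100 unit distance. Movers landing outside every
# patch die. Returns the destination patch id per individual (NA = died).
disperse_patches <- function(source, d, landscape, max_dist = 100) {
  n <- length(source)
  if (!n) return(integer(0))
  dest <- as.integer(source)
  move <- stats::runif(n) < d
  m <- sum(move)
  if (!m) return(dest)
  src <- source[move]
  # uniform origin within the source disc
  rr <- landscape$radius * sqrt(stats::runif(m))
  th <- stats::runif(m, 0, 2 * pi)
  x0 <- landscape$centers[src, 1] + rr * cos(th)
  y0 <- landscape$centers[src, 2] + rr * sin(th)
  phi <- stats::runif(m, 0, 2 * pi)
  dist <- stats::runif(m, 0, max_dist)
  x1 <- x0 + dist * cos(phi)
  y1 <- y0 + dist * sin(phi)
  land <- rep(NA_integer_, m)
  r2 <- landscape$radius^2
  for (p in 1:3) {
    inp <- is.na(land) &
      (x1 - landscape$centers[p, 1])^2 + (y1 - landscape$centers[p, 2])^2 <= r2
    land[inp] <- p
  }
  dest[move] <- land
  dest
}

#' Attempt passive dispersal
#'
#' With probability `1 - d` an individual stays in its source patch.
#' Otherwise it departs from a uniform-random point inside the source patch
#' at a uniform angle in `[0, 2*pi)` for a uniform distance in
#' `[0, max_dist]` (default 0-100 units). If the endpoint falls inside any
#' patch — including the source — the individual settles there; individuals
#' that land between patches die immediately.
#'
#' @param n number of independent dispersal attempts to simulate.
#' @param source source patch index (1-3).
#' @param d dispersal probability in `[0, 1]`.
#' @param landscape an `nc_landscape`.
#' @param max_dist maximum dispersal distance (default 100).
#' @return integer vector of length `n`: destination patch per individual,
#'   `NA` for dispersal death.
#' @export
attempt_dispersal <- function(n = 1, source, d, landscape, max_dist = 100) {
  if (d < 0 || d > 1) stop("`d` must be in [0, 1]")
  disperse_patches(rep(as.integer(source), n), d, landscape, max_dist)
}
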