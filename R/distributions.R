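#' Distance grid for interspin distance distributions
#'
#' A uniform grid of interspin distances on which distance distributions
#' are represented. The default window of 15--80 Angstrom is the range
#' over which pulsed dipolar EPR on nitroxide pairs resolves distances.
#'
#' @param r_min Lower edge of the window (Angstrom).
#' @param r_max Upper edge of the window (Angstrom).
#' @param n_points Number of grid points (>= 2); the default 131 gives a
#'   0.5 Angstrom step on the default window.
#'
#' @return An object of class `distance_grid` with elements `r_min`,
#'   `r_max`, `n_points`, `r` (the grid values) and `dr` (the step).
#' @export
#' @examples
#' g <- distance_grid()
#' range(g$r)
distance_grid <- function(r_min = 15, r_max = 80, n_points = 131) {
  stopifnot(is.numeric(r_min), is.numeric(r_max), r_min > 0)
  if (r_min >= r_max) stop("r_min must be smaller than r_max")
  if (n_points < 2) stop("n_points must be at least 2")
  r <- seq(r_min, r_max, length.out = n_points)
  structure(
    list(r_min = r_min, r_max = r_max, n_points = as.integer(n_points),
         r = r, dr = r[2] - r[1]),
    class = "distance_grid"
  )
}

#' Gridded distance distribution P(r)
#'
#' Probability density over interspin distance on a fixed grid. The
#' density is non-negative and normalized so that its trapezoidal
#' integral over the grid equals one.
#'
#' @param grid A [distance_grid()].
#' @param density Non-negative density values, one per grid point
#'   (1/Angstrom). Normalized on construction.
#'
#' @return An object of class `distance_distribution` with elements
#'   `grid` and `density`.
#' @export
distance_distribution <- function(grid, density) {
  stopifnot(inherits(grid, "distance_grid"))
  density <- as.numeric(density)
  if (length(density) != grid$n_points)
    stop("density must have one value per grid point")
  if (any(!is.finite(density))) stop("density must be finite")
  if (any(density < -1e-12)) stop("density must be non-negative")
  density[density < 0] <- 0
  z <- trapz_grid(grid, density)
  if (z <= 0) stop("density integrates to zero; cannot normalize")
  structure(list(grid = grid, density = density / z),
            class = "distance_distribution")
}

# Trapezoidal integral of values sampled on a distance grid.
trapz_grid <- function(grid, values) {
  pracma::trapz(grid$r, values)
}

# Trapezoidal quadrature weights for a uniform grid (vector, sums to
# the window width).
trapz_weights <- function(grid) {
  w <- rep(grid$dr, grid$n_points)
  w[c(1, grid$n_points)] <- grid$dr / 2
  w
}

#' Two-state bi-Gaussian distance model
#'
#' Parametric two-component Gaussian model of a distance distribution:
#' a compact state centered at `r1` and an extended state at `r2`, with
#' populations `p1` and `1 - p1`. Components are sorted so that index 1
#' is always the shorter-distance (compact) state.
#'
#' @param r1,r2 Component centers (Angstrom).
#' @param sigma1,sigma2 Component standard deviations (Angstrom), > 0.
#' @param p1 Population of the first (compact) component, in \[0, 1\].
#'
#' @return An object of class `bigaussian_model` with fields `r1`,
#'   `sigma1`, `p1`, `r2`, `sigma2` and derived `p2 = 1 - p1`.
#' @export
#' @examples
#' m <- bigaussian_model(r1 = 22, sigma1 = 1.5, p1 = 0.68,
#'                       r2 = 45, sigma2 = 8)
#' m$p2
bigaussian_model <- function(r1, sigma1, p1, r2, sigma2) {
  stopifnot(sigma1 > 0, sigma2 > 0)
  if (p1 < 0 || p1 > 1) stop("p1 must lie in [0, 1]")
  if (r1 > r2) {  # enforce compact = shorter distance
    tmp <- c(r1, sigma1); r1 <- r2; sigma1 <- sigma2
    r2 <- tmp[1]; sigma2 <- tmp[2]; p1 <- 1 - p1
  }
  structure(list(r1 = r1, sigma1 = sigma1, p1 = p1,
                 r2 = r2, sigma2 = sigma2, p2 = 1 - p1),
            class = "bigaussian_model")
}

#' Evaluate a bi-Gaussian model on a distance grid
#'
#' @param model A [bigaussian_model()].
#' @param grid A [distance_grid()].
#' @return A [distance_distribution()] (renormalized on the grid, so
#'   mass truncated outside the window is redistributed).
#' @export
as_distribution <- function(model, grid = distance_grid()) {
  stopifnot(inherits(model, "bigaussian_model"))
  d <- model$p1 * stats::dnorm(grid$r, model$r1, model$sigma1) +
    model$p2 * stats::dnorm(grid$r, model$r2, model$sigma2)
  distance_distribution(grid, d)
}

#' @export
print.bigaussian_model <- function(x, ...) {
  cat(sprintf(
    "bi-Gaussian model: compact r1 = %.2f A (sigma %.2f, p1 = %.3f); extended r2 = %.2f A (sigma %.2f, p2 = %.3f)\n",
    x$r1, x$sigma1, x$p1, x$r2, x$sigma2, x$p2))
  invisible(x)
}

#' @export
print.distance_distribution <- function(x, ...) {
  cat(sprintf(
    "distance distribution on [%.1f, %.1f] A (%d points), <r> = %.2f A\n",
    x$grid$r_min, x$grid$r_max, x$grid$n_points,
    trapz_grid(x$grid, x$grid$r * x$density)))
  invisible(x)
}
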