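#' Cartesian to cylindrical coordinates
#'
#' Maps `(x, y, z)` to `(r, theta, z)` with `r = sqrt(x^2 + y^2)` and the
#' azimuth resolved by explicit branches so that `theta` always lies in
#' `[0, 2*pi)`: `pi/2` for `x = 0, y > 0`; `3*pi/2` for `x = 0, y < 0`;
#' `atan(y/x)` for `x > 0, y >= 0`; `pi + atan(y/x)` for `x < 0`;
#' `2*pi + atan(y/x)` for `x > 0, y < 0`. On the axis (`x = y = 0`) the
#' azimuth is undefined and is assigned 0; ventricular walls never contain
#' the long axis, so this only guards degenerate synthetic input.
#'
#' @param p numeric length-3 point or an `n x 3` matrix (mm).
#' @return same shape with columns `(r, theta, z)` (mm, radians, mm).
#' @export
to_cylindrical <- function(p) {
  vec <- is.null(dim(p))
  m <- if (vec) matrix(p, ncol = 3L) else as.matrix(p)
  if (any(!is.finite(m))) stop("validation error: non-finite coordinates")
  x <- m[, 1L]; y <- m[, 2L]
  r <- sqrt(x^2 + y^2)
  th <- numeric(length(x))
  th[x == 0 & y > 0] <- pi / 2
  th[x == 0 & y < 0] <- 3 * pi / 2
  i <- x > 0 & y >= 0; th[i] <- atan(y[i] / x[i])
  i <- x < 0;          th[i] <- pi + atan(y[i] / x[i])
  i <- x > 0 & y < 0;  th[i] <- 2 * pi + atan(y[i] / x[i])
  th[x == 0 & y == 0] <- 0
  th <- th %% (2 * pi)
  out <- cbind(r, th, m[, 3L])
  colnames(out) <- c("r", "theta", "z")
  if (vec) drop(out) else out
}

#' Cylindrical to Cartesian coordinates
#'
#' Inverse of [to_cylindrical()]: `(r cos(theta), r sin(theta), z)`.
#'
#' @param cp numeric length-3 `(r, theta, z)` or an `n x 3` matrix.
#' @return Cartesian point(s) of the same shape.
#' @export
from_cylindrical <- function(cp) {
  vec <- is.null(dim(cp))
  m <- if (vec) matrix(cp, ncol = 3L) else as.matrix(cp)
  if (any(m[, 1L] < 0)) stop("validation error: negative radius")
  out <- cbind(m[, 1L] * cos(m[, 2L]), m[, 1L] * sin(m[, 2L]), m[, 3L])
  colnames(out) <- c("x", "y", "z")
  if (vec) drop(out) else out
}

#' Cylindrical-coordinate representation of a solid model
#'
#' Transforms each Cartesian control point to `(r, theta, z)` and unwraps
#' `theta` along the circumferential control index (adding multiples of
#' `2*pi`) so consecutive control angles are continuous — required for the
#' angular control values to define a smooth spline. The cylindrical model
#' shares the Cartesian model's knot vectors; the transform acts on control
#' values, so spline-evaluated `(r, theta, z)` fields approximate, but do not
#' pointwise equal, the transformed Cartesian surface.
#'
#' @param solid a Cartesian [solid_model()] with all control points off-axis.
#' @return a [solid_model()] with `coords = "cylindrical"`.
#' @export
solid_to_cylindrical <- function(solid) {
  stopifnot(inherits(solid, "solid_model"))
  if (solid$coords != "cartesian")
    stop("validation error: solid is already cylindrical")
  d <- dim(solid$grid)
  g <- array(0, d)
  for (j in seq_len(d[2L])) for (l in seq_len(d[3L])) {
    pts <- solid$grid[, j, l, , drop = TRUE]
    pts <- matrix(pts, ncol = 3L)
    cyl <- to_cylindrical(pts)
    if (any(cyl[, 1L] <= 0))
      stop("validation error: on-axis control point (r = 0) at long-axis index ",
           j, ", radial index ", l)
    th <- .unwrap_angles(cyl[, 2L])
    g[, j, l, 1L] <- cyl[, 1L]
    g[, j, l, 2L] <- th
    g[, j, l, 3L] <- cyl[, 3L]
  }
  solid_model(g, solid$knots_c, solid$knots_l, solid$knots_r,
              coords = "cylindrical")
}

# add 2*pi multiples so successive angles never jump by more than pi
.unwrap_angles <- function(th) {
  if (length(th) < 2L) return(th)
  d <- diff(th)
  adj <- cumsum(round(d / (2 * pi))) * 2 * pi
  th[-1L] <- th[-1L] - adj
  th
}
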