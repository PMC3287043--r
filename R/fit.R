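#' Least-squares B-spline surface fit of a wall point cloud
#'
#' Fits a tensor-product B-spline surface, periodic in the circumferential
#' direction, by linear least squares over a fixed `(t, w)` parameterization:
#' minimizes `sum_p ||S(t_p, w_p) - x_p||^2` for the control net. The
#' parameterization defaults to [parameterize_cloud()]; passing the
#' parameters of a reference phase explicitly keeps material correspondence
#' across a deformation sequence, and passing `knots_w` reuses a reference
#' phase's longitudinal knots.
#'
#' @param cloud a [wall_cloud()].
#' @param net_size integer length-2 `(n+1, m+1)`: unique circumferential and
#'   longitudinal control counts.
#' @param degrees integer length-2 spline degrees, default cubic.
#' @param params optional data frame with columns `t`, `w` (one row per
#'   point) overriding [parameterize_cloud()].
#' @param knots_w optional open-clamped [knot_vector()] for the longitudinal
#'   direction; by default built with [make_knot_vector()] over averaged
#'   point parameters.
#' @param knot_method interior-knot placement for the longitudinal direction.
#' @return a [surface_model()] with attribute `rms_residual` (mm) and the
#'   parameters used as attribute `params`.
#' @export
fit_surface <- function(cloud, net_size, degrees = c(3L, 3L), params = NULL,
                        knots_w = NULL, knot_method = "riesenfeld") {
  stopifnot(inherits(cloud, "wall_cloud"))
  net_size <- as.integer(net_size); degrees <- as.integer(degrees)
  nc <- net_size[1L]; nm <- net_size[2L]
  if (is.null(params)) params <- parameterize_cloud(cloud)
  P <- nrow(cloud$points)
  if (nrow(params) != P)
    stop("validation error: parameterization rows must match point count")
  nslice <- length(unique(cloud$slice))
  if (min(table(cloud$slice)) < nc || nslice < nm)
    stop("validation error: cloud too sparse for net ", nc, " x ", nm,
         " (need >= net points per direction)")
  kt <- periodic_knot_vector(nc, degrees[1L])
  if (is.null(knots_w)) {
    # averaged node parameters: nm quantile-spaced representatives of w
    wn <- sort(unique(round(params$w, 12)))
    nodes <- if (length(wn) >= nm) {
      stats::quantile(wn, probs = seq(0, 1, length.out = nm), names = FALSE,
                      type = 7)
    } else seq(0, 1, length.out = nm)
    nodes <- sort(unique(nodes))
    if (length(nodes) < nm) nodes <- seq(0, 1, length.out = nm)
    knots_w <- make_knot_vector(nodes, degrees[2L], knot_method)
  }
  if (knots_w$degree != degrees[2L] || n_basis(knots_w) != nm)
    stop("validation error: knots_w inconsistent with net size / degree")

  Mc <- t(vapply(params$t, function(ti) .ctrl_basis(kt, ti, nc, 0L), numeric(nc)))
  Mw <- t(vapply(params$w, function(wi) .ctrl_basis(knots_w, wi, nm, 0L), numeric(nm)))
  A <- Mc[, rep(seq_len(nc), nm), drop = FALSE] *
       Mw[, rep(seq_len(nm), each = nc), drop = FALSE]
  qra <- qr(A)
  if (qra$rank < ncol(A))
    stop("validation error: rank-deficient normal equations (rank ", qra$rank,
         " < ", ncol(A), "); try a smaller control net")
  coefs <- qr.coef(qra, cloud$points)
  resid <- cloud$points - A %*% coefs
  net <- array(coefs, dim = c(nc, nm, 3L))
  surf <- surface_model(net, kt, knots_w)
  attr(surf, "rms_residual") <- sqrt(mean(rowSums(resid^2)))
  attr(surf, "params") <- params
  surf
}

#' Hexahedral control mesh swept between two wall surfaces
#'
#' Builds the layered control lattice of the myocardial wall: radial layer
#' `q` (`q = 0..L-1`) is the linear blend
#' `(1 - q/(L-1)) * inner + (q/(L-1)) * outer` of matched control points, so
#' layer 0 is exactly the endocardial net and the last layer exactly the
#' epicardial net.
#'
#' @param inner,outer [surface_model()]s sharing net size, degrees, and knot
#'   vectors.
#' @param radial_layers integer number of radial control layers, >= 2.
#' @return object of class `hex_mesh`: the control array with the surfaces'
#'   knot vectors attached.
#' @export
sweep_hex_mesh <- function(inner, outer, radial_layers = 4L) {
  stopifnot(inherits(inner, "surface_model"), inherits(outer, "surface_model"))
  L <- as.integer(radial_layers)
  if (L < 2L) stop("validation error: radial_layers must be >= 2")
  if (!identical(dim(inner$net), dim(outer$net)) ||
      !identical(inner$degrees, outer$degrees) ||
      !isTRUE(all.equal(inner$knots_t$values, outer$knots_t$values)) ||
      !isTRUE(all.equal(inner$knots_w$values, outer$knots_w$values)))
    stop("validation error: inner and outer surfaces must share net size, degrees and knots")
  ri <- sqrt(inner$net[, , 1L]^2 + inner$net[, , 2L]^2)
  ro <- sqrt(outer$net[, , 1L]^2 + outer$net[, , 2L]^2)
  ncross <- sum(ri > ro)
  if (ncross > 0L)
    warning("crossing walls: inner control radius exceeds outer at ", ncross,
            " matched control points")
  d <- dim(inner$net)
  grid <- array(0, c(d[1L], d[2L], L, 3L))
  for (q in seq_len(L)) {
    b <- (q - 1) / (L - 1)
    grid[, , q, ] <- (1 - b) * inner$net + b * outer$net
  }
  structure(list(grid = grid, knots_t = inner$knots_t, knots_w = inner$knots_w,
                 degrees = inner$degrees, crossing = ncross),
            class = "hex_mesh")
}

#' @export
print.hex_mesh <- function(x, ...) {
  d <- dim(x$grid)
  cat(sprintf("<hex_mesh> %d x %d x %d control lattice (circumferential x long-axis x radial)\n",
              d[1], d[2], d[3]))
  invisible(x)
}

#' Trivariate B-spline solid from a hexahedral control mesh
#'
#' Adopts the swept control lattice as the solid's control grid, reusing the
#' surfaces' circumferential and longitudinal knot vectors and building the
#' radial knot vector with [make_knot_vector()] over uniformly spaced layer
#' parameters. Evaluation then maps the unit parameter cube into the wall
#' volume.
#'
#' @param mesh a `hex_mesh` from [sweep_hex_mesh()].
#' @param degree_r radial spline degree (default cubic; requires at least
#'   `degree_r + 1` radial layers).
#' @param knot_method radial interior-knot placement method.
#' @return a Cartesian [solid_model()].
#' @export
fit_solid <- function(mesh, degree_r = 3L, knot_method = "riesenfeld") {
  stopifnot(inherits(mesh, "hex_mesh"))
  degree_r <- as.integer(degree_r)
  nr <- dim(mesh$grid)[3L]
  if (nr < degree_r + 1L)
    stop("validation error: ", nr, " radial layers cannot carry degree ",
         degree_r, " (need >= degree+1)")
  kr <- make_knot_vector(seq(0, 1, length.out = nr), degree_r, knot_method)
  solid_model(mesh$grid, mesh$knots_t, mesh$knots_w, kr)
}
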