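#' Tensor-product B-spline surface model
#'
#' `S(t, w) = sum_i sum_j p_ij N_{i,k1}(t) N_{j,k2}(w)` over an
#' `(n+1) x (m+1)` control net. The first (circumferential) direction may be
#' periodic, in which case the net stores only the unique control columns and
#' evaluation wraps.
#'
#' @param net numeric array `nc x nm x 3` of control points (mm).
#' @param knots_t,knots_w [knot_vector()]s for the two directions.
#' @return object of class `surface_model`.
#' @export
surface_model <- function(net, knots_t, knots_w) {
  net <- .as_ctrl_array(net, 2L)
  .check_kv_dim(knots_t, dim(net)[1L], "t (circumferential)")
  .check_kv_dim(knots_w, dim(net)[2L], "w (long-axis)")
  structure(list(net = net, knots_t = knots_t, knots_w = knots_w,
                 degrees = c(knots_t$degree, knots_w$degree)),
            class = "surface_model")
}

#' Trivariate B-spline solid model
#'
#' `V(t, w, u) = sum_i sum_j sum_k p_ijk N_{i,k1}(t) N_{j,k2}(w) N_{k,k3}(u)`
#' over an `(n+1) x (m+1) x (l+1)` control grid. Directions are named
#' circumferential (`t`, may be periodic), long-axis (`w`) and radial (`u`),
#' mapping the unit parameter cube into the myocardial wall volume.
#'
#' @param grid numeric array `nc x nl x nr x 3` of control points. Coordinates
#'   are Cartesian (mm) unless `coords = "cylindrical"`, in which case the
#'   three control values are `(r, theta, z)`.
#' @param knots_c,knots_l,knots_r [knot_vector()]s (circumferential,
#'   long-axis, radial).
#' @param coords `"cartesian"` or `"cylindrical"` tag for the control values.
#' @return object of class `solid_model`.
#' @export
solid_model <- function(grid, knots_c, knots_l, knots_r, coords = "cartesian") {
  grid <- .as_ctrl_array(grid, 3L)
  if (knots_l$form == "periodic" || knots_r$form == "periodic")
    stop("validation error: long-axis and radial directions must be open-clamped")
  .check_kv_dim(knots_c, dim(grid)[1L], "circumferential")
  .check_kv_dim(knots_l, dim(grid)[2L], "long-axis")
  .check_kv_dim(knots_r, dim(grid)[3L], "radial")
  coords <- match.arg(coords, c("cartesian", "cylindrical"))
  structure(list(grid = grid, knots_c = knots_c, knots_l = knots_l,
                 knots_r = knots_r,
                 degrees = c(knots_c$degree, knots_l$degree, knots_r$degree),
                 coords = coords),
            class = "solid_model")
}

#' @export
print.surface_model <- function(x, ...) {
  d <- dim(x$net)
  cat(sprintf("<surface_model> net %d x %d, degrees (%d, %d), t-direction %s\n",
              d[1], d[2], x$degrees[1], x$degrees[2], x$knots_t$form))
  if (!is.null(attr(x, "rms_residual")))
    cat(sprintf("  fit RMS residual: %.4g mm\n", attr(x, "rms_residual")))
  invisible(x)
}

#' @export
print.solid_model <- function(x, ...) {
  d <- dim(x$grid)
  cat(sprintf(
    "<solid_model> grid %d x %d x %d (%s), degrees (%d, %d, %d), circumferential %s\n",
    d[1], d[2], d[3], x$coords, x$degrees[1], x$degrees[2], x$degrees[3],
    x$knots_c$form))
  invisible(x)
}

.as_ctrl_array <- function(a, ndir) {
  a <- unclass(a)
  if (!is.array(a) || length(dim(a)) != ndir + 1L || dim(a)[ndir + 1L] != 3L)
    stop("validation error: control points must be an array with a trailing dimension of 3")
  storage.mode(a) <- "double"
  if (any(!is.finite(a)))
    stop("validation error: non-finite control-point coordinates")
  d <- dim(a)[seq_len(ndir)]
  if (any(d < 1L)) stop("validation error: empty control dimension")
  a
}

.check_kv_dim <- function(kv, nctrl, label) {
  stopifnot(inherits(kv, "knot_vector"))
  need <- if (kv$form == "periodic") nctrl + kv$degree else nctrl
  if (n_basis(kv) != need)
    stop(sprintf(
      "validation error: %s knot vector has %d basis functions but control dimension is %d (%s)",
      label, n_basis(kv), nctrl, kv$form))
  if (kv$form == "open" && nctrl < kv$degree + 1L)
    stop(sprintf("validation error: %s direction needs at least degree+1 control points", label))
  invisible(TRUE)
}

#' Evaluate a B-spline curve
#'
#' `C(t) = sum_i p_i N_{i,k}(t)`: a convex combination of the control points
#' at interior parameters; open-clamped curves interpolate their end control
#' points.
#'
#' @param control numeric matrix `n x d` of control points (rows), or a
#'   numeric vector for a scalar-valued spline.
#' @param knots a [knot_vector()]; periodic knot vectors wrap the control
#'   points.
#' @param t numeric parameters.
#' @param deriv derivative order, 0 or 1.
#' @return matrix `length(t) x d` of curve points (or a vector if `control`
#'   is a vector).
#' @export
evaluate_curve <- function(control, knots, t, deriv = 0L) {
  vec <- is.null(dim(control))
  cm <- if (vec) matrix(control, ncol = 1L) else as.matrix(control)
  out <- t(vapply(as.numeric(t), function(ti) {
    b <- .ctrl_basis(knots, ti, nrow(cm), deriv)
    drop(b %*% cm)
  }, numeric(ncol(cm))))
  if (vec) drop(out) else out
}

# core trivariate contraction: basis rows in each direction against a
# (nc x nl x nr x ncomp) array; deriv is a length-3 vector of 0/1
.tensor_eval3 <- function(grid, kc, kl, kr, t, w, u, deriv = c(0L, 0L, 0L)) {
  d <- dim(grid)
  bc <- .ctrl_basis(kc, t, d[1L], deriv[1L])
  bl <- .ctrl_basis(kl, w, d[2L], deriv[2L])
  br <- .ctrl_basis(kr, u, d[3L], deriv[3L])
  ncomp <- d[4L]
  out <- numeric(ncomp)
  for (q in seq_len(ncomp)) {
    m1 <- matrix(grid[, , , q], d[1L], d[2L] * d[3L])
    v1 <- matrix(drop(bc %*% m1), d[2L], d[3L])
    out[q] <- drop(bl %*% v1 %*% br)
  }
  out
}

.tensor_eval2 <- function(net, kt, kw, t, w, deriv = c(0L, 0L)) {
  d <- dim(net)
  bt <- .ctrl_basis(kt, t, d[1L], deriv[1L])
  bw <- .ctrl_basis(kw, w, d[2L], deriv[2L])
  vapply(seq_len(d[3L]), function(q) {
    drop(bt %*% net[, , q] %*% bw)
  }, numeric(1))
}

#' Evaluate a B-spline surface point
#'
#' @param surface a [surface_model()].
#' @param t,w scalar parameters in the evaluation domain.
#' @param deriv length-2 integer vector of derivative orders (0 or 1) in the
#'   two directions.
#' @return numeric length-3 point (mm), or a parametric derivative vector.
#' @export
evaluate_surface <- function(surface, t, w, deriv = c(0L, 0L)) {
  stopifnot(inherits(surface, "surface_model"))
  .tensor_eval2(surface$net, surface$knots_t, surface$knots_w, t, w,
                as.integer(deriv))
}

#' Evaluate a trivariate B-spline solid point
#'
#' @param solid a [solid_model()].
#' @param t,w,u scalar parameters (circumferential, long-axis, radial).
#' @param deriv length-3 integer vector of derivative orders (0 or 1).
#' @return numeric length-3 point (mm; or `(r, theta, z)` for cylindrical
#'   models), or a parametric derivative vector.
#' @export
evaluate_volume <- function(solid, t, w, u, deriv = c(0L, 0L, 0L)) {
  stopifnot(inherits(solid, "solid_model"))
  .tensor_eval3(solid$grid, solid$knots_c, solid$knots_l, solid$knots_r,
                t, w, u, as.integer(deriv))
}
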