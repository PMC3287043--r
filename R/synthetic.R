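#' Synthetic ventricle specification
#'
#' Parameters of a truncated prolate-spheroid stand-in for the left
#' ventricle, the canonical analytic geometry in cardiac modelling. The
#' inner (endocardial) and outer (epicardial) walls are spheroids with
#' semi-axes `(a, b, c)` (long axis along z, apex at `z = -c`); slices mimic
#' short-axis MRI coverage of the fraction `truncation` of the inner long
#' axis measured from the apex, the basal cap being removed.
#'
#' Defaults emulate an adult human left ventricle at end diastole: inner
#' semi-axes 20 x 20 x 45 mm, outer 30 x 30 x 55 mm (10 mm equatorial wall),
#' 12 slices of 32 points, no noise.
#'
#' @param inner,outer length-3 semi-axes `(a, b, c)` in mm; `outer` must
#'   exceed `inner` componentwise.
#' @param truncation fraction of the inner long axis retained from the apex,
#'   in (0, 1).
#' @param slices number of short-axis slices, >= 3.
#' @param points_per_slice contour points per slice, >= 8.
#' @param noise_sigma isotropic Gaussian noise s.d. in mm, applied after
#'   on-surface placement.
#' @param seed integer seed for the noise stream.
#' @return object of class `ventricle_spec`.
#' @export
ventricle_spec <- function(inner = c(20, 20, 45), outer = c(30, 30, 55),
                           truncation = 0.85, slices = 12L,
                           points_per_slice = 32L, noise_sigma = 0,
                           seed = 1L) {
  if (length(inner) != 3L || length(outer) != 3L ||
      any(!is.finite(c(inner, outer))) || any(inner <= 0))
    stop("validation error: semi-axes must be finite positive length-3 vectors")
  if (any(outer <= inner))
    stop("validation error: outer semi-axes must exceed inner componentwise")
  if (truncation <= 0 || truncation >= 1)
    stop("validation error: truncation fraction must lie in (0, 1)")
  slices <- as.integer(slices); points_per_slice <- as.integer(points_per_slice)
  if (slices < 3L) stop("validation error: need at least 3 slices")
  if (points_per_slice < 8L) stop("validation error: need at least 8 points per slice")
  if (!is.finite(noise_sigma) || noise_sigma < 0)
    stop("validation error: noise_sigma must be a nonnegative length in mm")
  structure(list(inner = as.numeric(inner), outer = as.numeric(outer),
                 truncation = truncation, slices = slices,
                 points_per_slice = points_per_slice,
                 noise_sigma = as.numeric(noise_sigma),
                 seed = as.integer(seed)),
            class = "ventricle_spec")
}

# run code with a fixed RNG state, restoring the caller's stream afterwards
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate synthetic wall point clouds
#'
#' Places `slices` slice planes equally spaced over the truncated long-axis
#' range of the inner spheroid (the exact apex excluded, where cross-sections
#' degenerate), and on each plane `points_per_slice` points equally spaced in
#' angle on the wall's cross-section ellipse, plus seeded isotropic Gaussian
#' noise.
#'
#' @param spec a [ventricle_spec()].
#' @param phase cardiac-phase index stamped on the clouds.
#' @return list with elements `inner` and `outer`, each a [wall_cloud()].
#' @export
generate_walls <- function(spec, phase = 0L) {
  stopifnot(inherits(spec, "ventricle_spec"))
  ci <- spec$inner[3L]
  z_top <- ci * (2 * spec$truncation - 1)          # basal truncation plane
  zs <- -ci + seq_len(spec$slices) / spec$slices * (z_top + ci)
  .with_seed(spec$seed, {
    mk <- function(ax, wall) {
      pps <- spec$points_per_slice
      th <- 2 * pi * (seq_len(pps) - 1L) / pps
      pts <- NULL; slice <- NULL
      for (s in seq_along(zs)) {
        f <- sqrt(pmax(0, 1 - (zs[s] / ax[3L])^2))
        pts <- rbind(pts, cbind(ax[1L] * f * cos(th), ax[2L] * f * sin(th),
                                rep(zs[s], pps)))
        slice <- c(slice, rep(s - 1L, pps))
      }
      if (spec$noise_sigma > 0)
        pts <- pts + matrix(stats::rnorm(length(pts), sd = spec$noise_sigma),
                            nrow(pts), 3L)
      wall_cloud(pts, slice = slice,
                 ring = rep(seq_len(spec$points_per_slice) - 1L, spec$slices),
                 wall = wall, phase = phase)
    }
    list(inner = mk(spec$inner, "inner"), outer = mk(spec$outer, "outer"))
  })
}

#' Prescribed deformation specification
#'
#' Analytic deformations used to build adjacent-phase sequences with known
#' ground truth:
#' \describe{
#'   \item{translation}{adds the constant vector `magnitude` (length 3, mm).}
#'   \item{dilation}{scales about `about` by `1 + magnitude`.}
#'   \item{torsion}{rotates each point about the long (z) axis through
#'     `about` by angle `magnitude * (z - about[3])` (magnitude in rad/mm).}
#'   \item{radial_contraction}{scales `(x, y)` about the axis by
#'     `1 - magnitude`, leaving z fixed.}
#' }
#'
#' @param mode deformation mode.
#' @param magnitude mode-dependent scalar (or length-3 vector for
#'   translation).
#' @param about reference origin/axis point, default the origin.
#' @return object of class `deformation_spec`.
#' @export
deformation_spec <- function(mode = c("translation", "dilation", "torsion",
                                      "radial_contraction"),
                             magnitude, about = c(0, 0, 0)) {
  mode <- match.arg(mode)
  magnitude <- as.numeric(magnitude)
  if (any(!is.finite(magnitude)))
    stop("validation error: magnitude must be finite")
  if (mode == "translation") {
    if (!length(magnitude) %in% c(1L, 3L))
      stop("validation error: translation magnitude must have length 1 or 3")
    if (length(magnitude) == 1L) magnitude <- rep(magnitude, 3L)
  } else if (length(magnitude) != 1L) {
    stop("validation error: ", mode, " magnitude must be scalar")
  }
  if (mode %in% c("dilation", "radial_contraction") && magnitude <= -1)
    stop("validation error: scaling fraction must exceed -1")
  structure(list(mode = mode, magnitude = magnitude, about = as.numeric(about)),
            class = "deformation_spec")
}

.deform_points <- function(pts, d) {
  a <- d$about
  switch(d$mode,
    translation = sweep(pts, 2L, d$magnitude, "+"),
    dilation = {
      sweep(sweep(pts, 2L, a, "-") * (1 + d$magnitude), 2L, a, "+")
    },
    torsion = {
      x <- pts[, 1L] - a[1L]; y <- pts[, 2L] - a[2L]
      phi <- d$magnitude * (pts[, 3L] - a[3L])
      cbind(a[1L] + x * cos(phi) - y * sin(phi),
            a[2L] + x * sin(phi) + y * cos(phi),
            pts[, 3L])
    },
    radial_contraction = {
      x <- pts[, 1L] - a[1L]; y <- pts[, 2L] - a[2L]
      cbind(a[1L] + (1 - d$magnitude) * x, a[2L] + (1 - d$magnitude) * y,
            pts[, 3L])
    })
}

#' Apply a prescribed deformation
#'
#' For a [wall_cloud()] the map acts on the points; for a Cartesian
#' [solid_model()] it acts on the control points (exact for the affine
#' modes, since affine maps commute with the spline expansion).
#'
#' @param x a [wall_cloud()] or Cartesian [solid_model()].
#' @param d a [deformation_spec()].
#' @return deformed object of the same type.
#' @export
apply_deformation <- function(x, d) {
  stopifnot(inherits(d, "deformation_spec"))
  if (inherits(x, "wall_cloud")) {
    x$points <- .deform_points(x$points, d)
    x
  } else if (inherits(x, "solid_model")) {
    if (x$coords != "cartesian")
      stop("validation error: deformation acts on Cartesian solids")
    g <- x$grid
    dm <- dim(g)
    pts <- matrix(g, prod(dm[1:3]), 3L)
    x$grid <- array(.deform_points(pts, d), dm)
    x
  } else stop("validation error: cannot deform object of class ", class(x)[1L])
}

#' Analytic infinitesimal strain of a prescribed deformation
#'
#' Closed-form Voigt strain of the deformation's displacement field at a
#' point: zero for translation; `(m, m, m, 0, 0, 0)` for dilation `m`;
#' `(-m, -m, 0, 0, 0, 0)` for radial contraction `m`; for torsion rate
#' `tau` (rad/mm) the engineering shears `gamma_yz = tau * x`,
#' `gamma_xz = -tau * y` (small-rotation limit).
#'
#' @param d a [deformation_spec()].
#' @param point numeric length-3 Cartesian point (mm).
#' @return a [strain_state()].
#' @export
ground_truth_strain <- function(d, point) {
  stopifnot(inherits(d, "deformation_spec"))
  point <- as.numeric(point)
  a <- d$about
  m <- d$magnitude
  v <- switch(d$mode,
    translation = rep(0, 6L),
    dilation = c(m, m, m, 0, 0, 0),
    radial_contraction = c(-m, -m, 0, 0, 0, 0),
    torsion = c(0, 0, 0, 0, m * (point[1L] - a[1L]), -m * (point[2L] - a[2L])))
  strain_state(v)
}
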