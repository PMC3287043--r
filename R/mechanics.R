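#' Isotropic material parameters
#'
#' Defaults are the myocardial values used throughout the package's analyses:
#' elasticity modulus `E = 11` kPa and Poisson ratio `mu = 0.49` (nearly
#' incompressible passive myocardium).
#'
#' @param E elasticity modulus in kPa, > 0.
#' @param mu Poisson ratio, in `[0, 0.5)`; the elastic matrix is singular at
#'   the incompressible limit 0.5.
#' @return object of class `material_params`.
#' @export
material_params <- function(E = 11, mu = 0.49) {
  E <- as.numeric(E); mu <- as.numeric(mu)
  if (!is.finite(E) || E <= 0)
    stop("validation error: elasticity modulus E must be > 0")
  if (!is.finite(mu) || mu < 0 || mu >= 0.5)
    stop("validation error: Poisson ratio mu must lie in [0, 0.5) (incompressible limit excluded)")
  structure(list(E = E, mu = mu), class = "material_params")
}

#' @export
print.material_params <- function(x, ...) {
  cat(sprintf("<material_params> E = %g kPa, mu = %g\n", x$E, x$mu))
  invisible(x)
}

#' Isotropic linear-elastic stiffness matrix in Voigt notation
#'
#' The 6x6 matrix `D` relating Voigt strain
#' `(eps_x, eps_y, eps_z, gamma_xy, gamma_yz, gamma_xz)` to Voigt stress:
#' upper-left 3x3 block with 1 on the diagonal and `mu/(1-mu)` off-diagonal,
#' lower-right block `diag(H, H, H)` with `H = (1 - 2*mu) / (2*(1 - mu))`,
#' all scaled by `E*(1-mu) / ((1+mu)*(1-2*mu))`.
#'
#' @param mat a [material_params()].
#' @return symmetric positive-definite 6x6 numeric matrix (kPa).
#' @export
elastic_matrix <- function(mat) {
  stopifnot(inherits(mat, "material_params"))
  E <- mat$E; mu <- mat$mu
  H <- (1 - 2 * mu) / (2 * (1 - mu))
  A <- matrix(mu / (1 - mu), 3L, 3L)
  diag(A) <- 1
  D <- diag(c(1, 1, 1, H, H, H))
  D[1:3, 1:3] <- A
  E * (1 - mu) / ((1 + mu) * (1 - 2 * mu)) * D
}

#' Voigt strain and stress states
#'
#' Thin wrappers tagging a Voigt 6-vector. Strain packs
#' `(eps_x, eps_y, eps_z, gamma_xy, gamma_yz, gamma_xz)` with engineering
#' shears (sums of cross partial derivatives); stress packs
#' `(sigma_x, sigma_y, sigma_z, tau_xy, tau_yz, tau_xz)` in kPa.
#'
#' @param voigt numeric length-6 vector.
#' @return object of class `strain_state` / `stress_state`.
#' @export
strain_state <- function(voigt) {
  voigt <- as.numeric(voigt)
  if (length(voigt) != 6L || any(!is.finite(voigt)))
    stop("validation error: strain must be a finite Voigt 6-vector")
  names(voigt) <- c("eps_x", "eps_y", "eps_z", "gamma_xy", "gamma_yz", "gamma_xz")
  structure(list(voigt = voigt), class = "strain_state")
}

#' @rdname strain_state
#' @export
stress_state <- function(voigt) {
  voigt <- as.numeric(voigt)
  if (length(voigt) != 6L || any(!is.finite(voigt)))
    stop("validation error: stress must be a finite Voigt 6-vector")
  names(voigt) <- c("sigma_x", "sigma_y", "sigma_z", "tau_xy", "tau_yz", "tau_xz")
  structure(list(voigt = voigt), class = "stress_state")
}

#' Control-point displacement field bound to a solid model
#'
#' Displacements of the solid's control points between two cardiac phases;
#' the continuous displacement field interpolates them with the geometry's
#' own spline basis (isogeometric ansatz).
#'
#' @param solid the reference-phase [solid_model()] (Cartesian).
#' @param dx,dy,dz numeric rank-3 arrays of control displacements (mm), with
#'   the solid's control-grid dimensions.
#' @return object of class `displacement_field`.
#' @export
displacement_field <- function(solid, dx, dy, dz) {
  stopifnot(inherits(solid, "solid_model"))
  d <- dim(solid$grid)[1:3]
  for (a in list(dx, dy, dz))
    if (!identical(dim(a), d))
      stop("validation error: displacement arrays must match the control grid dimensions ",
           paste(d, collapse = " x "))
  darr <- array(0, c(d, 3L))
  darr[, , , 1L] <- dx; darr[, , , 2L] <- dy; darr[, , , 3L] <- dz
  structure(list(solid = solid, d = darr), class = "displacement_field")
}

#' @export
print.displacement_field <- function(x, ...) {
  d <- dim(x$d)
  cat(sprintf("<displacement_field> %d x %d x %d control displacements, max |d| = %.4g mm\n",
              d[1], d[2], d[3], max(abs(x$d))))
  invisible(x)
}

#' Displacement field between two phases of a solid model
#'
#' Solid models of adjacent time points reconstructed over the same control
#' topology differ only in their control points; the control-point-wise
#' difference `t1 - t0` is the displacement field of the isogeometric model,
#' bound to the earlier phase.
#'
#' @param solid_t0,solid_t1 [solid_model()]s sharing degrees, knot vectors
#'   and grid dimensions.
#' @return a [displacement_field()] bound to `solid_t0`.
#' @export
field_difference_displacements <- function(solid_t0, solid_t1) {
  stopifnot(inherits(solid_t0, "solid_model"), inherits(solid_t1, "solid_model"))
  if (!identical(dim(solid_t0$grid), dim(solid_t1$grid)) ||
      !identical(solid_t0$degrees, solid_t1$degrees) ||
      !isTRUE(all.equal(solid_t0$knots_c$values, solid_t1$knots_c$values)) ||
      !isTRUE(all.equal(solid_t0$knots_l$values, solid_t1$knots_l$values)) ||
      !isTRUE(all.equal(solid_t0$knots_r$values, solid_t1$knots_r$values)))
    stop("validation error: phases must share control topology (degrees, knots, grid dimensions)")
  dd <- solid_t1$grid - solid_t0$grid
  displacement_field(solid_t0, dd[, , , 1L], dd[, , , 2L], dd[, , , 3L])
}

#' Continuous displacement at a parameter point
#'
#' Tensor-product expansion of the control displacements:
#' `Disp(t_c, t_l, t_r) = sum d_ijl N_i(t_c) N_j(t_l) N_k(t_r)`.
#'
#' @param field a [displacement_field()].
#' @param t_c,t_l,t_r scalar parameters.
#' @param deriv length-3 derivative orders (0/1) per direction.
#' @return numeric `(DX, DY, DZ)` in mm (or its parametric derivative).
#' @export
displacement_at <- function(field, t_c, t_l, t_r, deriv = c(0L, 0L, 0L)) {
  stopifnot(inherits(field, "displacement_field"))
  s <- field$solid
  .tensor_eval3(field$d, s$knots_c, s$knots_l, s$knots_r, t_c, t_l, t_r,
                as.integer(deriv))
}

#' Parametric partial derivative of the solid geometry
#'
#' `d(x, y, z)/d t_direction` of the volumetric spline map: the
#' tensor-product derivative with the basis derivative taken in the chosen
#' direction only.
#'
#' @param solid a [solid_model()].
#' @param direction `"c"`, `"l"` or `"r"` (circumferential, long-axis,
#'   radial).
#' @param t_c,t_l,t_r scalar parameters.
#' @return numeric length-3 tangent vector (mm per unit parameter).
#' @export
geometry_partial <- function(solid, direction = c("c", "l", "r"), t_c, t_l, t_r) {
  direction <- match.arg(direction)
  dv <- c(c = 1L, l = 2L, r = 3L)[[direction]]
  deriv <- c(0L, 0L, 0L); deriv[dv] <- 1L
  evaluate_volume(solid, t_c, t_l, t_r, deriv = deriv)
}

#' Isoparametric Jacobian of the solid map
#'
#' `J` has rows `(x, y, z)` and columns `(t_c, t_l, t_r)`; a valid
#' ventricular solid has `det J > 0` throughout. Physical gradients of any
#' field expressed in the spline basis follow from parametric gradients via
#' the transpose-inverse of this matrix.
#'
#' @param solid a [solid_model()].
#' @param t_c,t_l,t_r scalar parameters.
#' @return list with `J` (3x3), `Jinv`, and `det`.
#' @export
jacobian_at <- function(solid, t_c, t_l, t_r) {
  J <- cbind(geometry_partial(solid, "c", t_c, t_l, t_r),
             geometry_partial(solid, "l", t_c, t_l, t_r),
             geometry_partial(solid, "r", t_c, t_l, t_r))
  dj <- det(J)
  if (abs(dj) < 1e-12)
    stop(sprintf("singular-mapping error: |det J| < 1e-12 at (t_c, t_l, t_r) = (%g, %g, %g)",
                 t_c, t_l, t_r))
  list(J = J, Jinv = solve(J), det = dj)
}

#' Physical gradient of one trivariate basis function
#'
#' Gradient of `N = N_i(t_c) N_j(t_l) N_k(t_r)` with respect to `(x, y, z)`:
#' the parametric gradient mapped through the inverse-transposed Jacobian of
#' the isoparametric solid map.
#'
#' @param solid a [solid_model()].
#' @param i,j,k 0-based basis indices in the three directions.
#' @param t_c,t_l,t_r scalar parameters (nonsingular Jacobian required).
#' @return numeric length-3 `(dN/dx, dN/dy, dN/dz)` (1/mm).
#' @export
basis_gradient_physical <- function(solid, i, j, k, t_c, t_l, t_r) {
  stopifnot(inherits(solid, "solid_model"))
  Nc <- basis_value(solid$knots_c, i, t_c)
  Nl <- basis_value(solid$knots_l, j, t_l)
  Nr <- basis_value(solid$knots_r, k, t_r)
  dNc <- basis_derivative(solid$knots_c, i, t_c)
  dNl <- basis_derivative(solid$knots_l, j, t_l)
  dNr <- basis_derivative(solid$knots_r, k, t_r)
  gpar <- c(dNc * Nl * Nr, Nc * dNl * Nr, Nc * Nl * dNr)
  jac <- jacobian_at(solid, t_c, t_l, t_r)
  drop(solve(t(jac$J), gpar))
}

#' Infinitesimal strain at a parameter point
#'
#' Assembles the Voigt strain from physical gradients of the isogeometric
#' displacement field: normal components `eps = du/dx` etc., engineering
#' shears `gamma_xy = du/dy + dv/dx` and cyclic.
#'
#' @param solid a Cartesian [solid_model()] (reference phase).
#' @param field a [displacement_field()] bound to `solid`.
#' @param t_c,t_l,t_r scalar parameters (nonsingular Jacobian required).
#' @return a [strain_state()].
#' @export
strain_at <- function(solid, field, t_c, t_l, t_r) {
  stopifnot(inherits(solid, "solid_model"), inherits(field, "displacement_field"))
  # rows: d/dt_c, d/dt_l, d/dt_r; cols: (u, v, w) displacement components
  Gt <- rbind(displacement_at(field, t_c, t_l, t_r, deriv = c(1L, 0L, 0L)),
              displacement_at(field, t_c, t_l, t_r, deriv = c(0L, 1L, 0L)),
              displacement_at(field, t_c, t_l, t_r, deriv = c(0L, 0L, 1L)))
  jac <- jacobian_at(solid, t_c, t_l, t_r)
  Gx <- solve(t(jac$J), Gt)    # rows: d/dx, d/dy, d/dz
  strain_state(c(Gx[1L, 1L], Gx[2L, 2L], Gx[3L, 3L],
                 Gx[2L, 1L] + Gx[1L, 2L],
                 Gx[3L, 2L] + Gx[2L, 3L],
                 Gx[3L, 1L] + Gx[1L, 3L]))
}

#' Stress at a parameter point
#'
#' Constitutive relation `sigma = D eps` applied to the strain of
#' [strain_at()].
#'
#' @inheritParams strain_at
#' @param mat a [material_params()].
#' @return a [stress_state()] (kPa).
#' @export
stress_at <- function(solid, field, mat, t_c, t_l, t_r) {
  eps <- strain_at(solid, field, t_c, t_l, t_r)
  stress_state(drop(elastic_matrix(mat) %*% eps$voigt))
}

#' Principal values and directions of a strain or stress state
#'
#' Eigen-decomposition of the symmetric 3x3 tensor reconstructed from the
#' Voigt vector: off-diagonals are `gamma/2` for strain (engineering shears
#' halved) and `tau` for stress. Values are returned in descending order with
#' orthonormal eigenvector columns.
#'
#' @param state a [strain_state()] or [stress_state()].
#' @return list with `values` (descending length-3) and `directions`
#'   (3x3, columns are unit eigenvectors).
#' @export
principal_values <- function(state) {
  v <- state$voigt
  half <- if (inherits(state, "strain_state")) 0.5 else 1
  Tm <- matrix(c(v[1], half * v[4], half * v[6],
                 half * v[4], v[2], half * v[5],
                 half * v[6], half * v[5], v[3]), 3L, 3L)
  e <- eigen(Tm, symmetric = TRUE)
  list(values = e$values, directions = e$vectors)
}

#' Sampled strain/stress field over the parameter cube
#'
#' Deterministic lattice sample of the solid: the circumferential direction
#' samples `[0, 1)` (the seam duplicate excluded for periodic models), the
#' other directions `[0, 1]`. The circumferential index varies fastest, then
#' long-axis, then radial (the ordering VTK structured grids expect).
#'
#' @param solid a Cartesian [solid_model()].
#' @param field a [displacement_field()] bound to `solid`.
#' @param mat a [material_params()].
#' @param resolution integer length-3 sample counts `(Nc, Nl, Nr)`, each
#'   >= 2.
#' @return data frame with parameter coordinates, position, `detJ`, the six
#'   strain and six stress components, and principal strains/stresses
#'   (descending `e1 >= e2 >= e3`, `s1 >= s2 >= s3`).
#' @export
evaluate_field_grid <- function(solid, field, mat, resolution = c(16L, 12L, 4L)) {
  resolution <- as.integer(resolution)
  if (length(resolution) != 3L || any(resolution < 2L))
    stop("validation error: resolution must be three integers >= 2")
  tc <- if (solid$knots_c$form == "periodic") {
    seq(0, 1, length.out = resolution[1L] + 1L)[seq_len(resolution[1L])]
  } else seq(0, 1, length.out = resolution[1L])
  tl <- seq(0, 1, length.out = resolution[2L])
  tr <- seq(0, 1, length.out = resolution[3L])
  n <- resolution[1L] * resolution[2L] * resolution[3L]
  out <- matrix(0, n, 3L + 3L + 1L + 6L + 6L + 3L + 3L)
  row <- 0L
  D <- elastic_matrix(mat)
  for (iu in seq_along(tr)) for (iw in seq_along(tl)) for (it in seq_along(tc)) {
    row <- row + 1L
    p <- evaluate_volume(solid, tc[it], tl[iw], tr[iu])
    jac <- jacobian_at(solid, tc[it], tl[iw], tr[iu])
    eps <- strain_at(solid, field, tc[it], tl[iw], tr[iu])
    sig <- drop(D %*% eps$voigt)
    pe <- principal_values(eps)$values
    ps <- principal_values(stress_state(sig))$values
    out[row, ] <- c(tc[it], tl[iw], tr[iu], p, jac$det, eps$voigt, sig, pe, ps)
  }
  df <- as.data.frame(out)
  names(df) <- c("tc", "tl", "tr", "x", "y", "z", "detJ",
                 "eps_x", "eps_y", "eps_z", "gamma_xy", "gamma_yz", "gamma_xz",
                 "sigma_x", "sigma_y", "sigma_z", "tau_xy", "tau_yz", "tau_xz",
                 "e1", "e2", "e3", "s1", "s2", "s3")
  attr(df, "resolution") <- resolution
  df
}

#' Volume of a solid model by Jacobian quadrature
#'
#' Integrates `det J` over the parameter cube with composite Gauss-Legendre
#' tensor quadrature, one rule per knot span and direction (the integrand is
#' piecewise polynomial across knot spans).
#'
#' @param solid a Cartesian [solid_model()].
#' @param quadrature_order Gauss-Legendre points per knot span per direction.
#' @return volume in cubic millimetres.
#' @export
integrate_volume <- function(solid, quadrature_order = 4L) {
  stopifnot(inherits(solid, "solid_model"))
  q <- as.integer(quadrature_order)
  if (q < 1L) stop("validation error: quadrature order must be >= 1")
  nodes <- function(kv) {
    dom <- kv_domain(kv)
    brk <- unique(kv$values[kv$values >= dom[1L] & kv$values <= dom[2L]])
    xs <- c(); ws <- c()
    for (s in seq_len(length(brk) - 1L)) {
      gl <- pracma::gaussLegendre(q, brk[s], brk[s + 1L])
      xs <- c(xs, gl$x); ws <- c(ws, gl$w)
    }
    list(x = xs, w = ws)
  }
  nc <- nodes(solid$knots_c); nl <- nodes(solid$knots_l); nr <- nodes(solid$knots_r)
  vol <- 0
  for (a in seq_along(nc$x)) for (b in seq_along(nl$x)) for (cc in seq_along(nr$x)) {
    dj <- jacobian_at(solid, nc$x[a], nl$x[b], nr$x[cc])$det
    if (dj < 0)
      stop(sprintf("singular-mapping error: negative det J at (%g, %g, %g)",
                   nc$x[a], nl$x[b], nr$x[cc]))
    vol <- vol + nc$w[a] * nl$w[b] * nr$w[cc] * dj
  }
  vol
}
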