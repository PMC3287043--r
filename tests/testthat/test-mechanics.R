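test_that("elastic matrix has the closed isotropic form and is SPD", {
  # mu = 0: D = diag(E, E, E, E/2, E/2, E/2)
  expect_equal(elastic_matrix(material_params(E = 7, mu = 0)),
               diag(c(7, 7, 7, 3.5, 3.5, 3.5)))
  # myocardial defaults: leading scalar from an independent arithmetic path
  mat <- material_params()
  expect_equal(mat$E, 11); expect_equal(mat$mu, 0.49)
  D <- elastic_matrix(mat)
  scal <- 11 * (1 - 0.49) / ((1 + 0.49) * (1 - 2 * 0.49))
  expect_equal(D[1, 1], scal)
  expect_equal(D[1, 2], scal * 0.49 / (1 - 0.49))
  expect_equal(D[4, 4], scal * (1 - 2 * 0.49) / (2 * (1 - 0.49)))
  expect_equal(D, t(D))
  expect_gt(min(eigen(D, symmetric = TRUE, only.values = TRUE)$values), 0)
  # SPD across the admissible range
  for (mu in c(0, 0.2, 0.45, 0.499)) {
    Dm <- elastic_matrix(material_params(E = 3, mu = mu))
    expect_gt(min(eigen(Dm, symmetric = TRUE, only.values = TRUE)$values), 0)
  }
  expect_error(material_params(mu = 0.5), "incompressible")
  expect_error(material_params(E = -1), "E must be > 0")
})

test_that("geometry partials are exact on affine solids and match finite differences", {
  cube <- unit_cube_solid()
  expect_equal(geometry_partial(cube, "c", 0.5, 0.5, 0.5), c(1, 0, 0))
  expect_equal(geometry_partial(cube, "l", 0.5, 0.5, 0.5), c(0, 1, 0))
  expect_equal(geometry_partial(cube, "r", 0.5, 0.5, 0.5), c(0, 0, 1))
  # affine image: partials are the columns of A
  A <- matrix(c(2, 0.5, 0, -0.3, 3, 1, 0, 0.2, 4), 3, 3)
  aff <- cube
  d <- dim(aff$grid)
  for (i in 1:d[1]) for (j in 1:d[2]) for (k in 1:d[3])
    aff$grid[i, j, k, ] <- A %*% cube$grid[i, j, k, ]
  for (p in list(c(0.2, 0.6, 0.8), c(0.5, 0.5, 0.5))) {
    expect_equal(geometry_partial(aff, "c", p[1], p[2], p[3]), A[, 1], tolerance = 1e-12)
    expect_equal(geometry_partial(aff, "l", p[1], p[2], p[3]), A[, 2], tolerance = 1e-12)
    expect_equal(geometry_partial(aff, "r", p[1], p[2], p[3]), A[, 3], tolerance = 1e-12)
  }
  withr::with_seed(37, {
    sol <- rand_solid()
    h <- 1e-6
    for (rep in 1:100) {
      p <- runif(3, 0.02, 0.98)
      gc <- geometry_partial(sol, "c", p[1], p[2], p[3])
      fd <- (evaluate_volume(sol, p[1] + h, p[2], p[3]) -
             evaluate_volume(sol, p[1] - h, p[2], p[3])) / (2 * h)
      expect_lt(max(abs(gc - fd)) / max(abs(gc)), 1e-5)
    }
  })
})

test_that("Jacobian assembly, determinant and inverse are consistent", {
  cube <- unit_cube_solid()
  j <- jacobian_at(cube, 0.5, 0.5, 0.5)
  expect_equal(j$J, diag(3))
  expect_equal(j$det, 1)
  scaled <- cube
  for (q in 1:3) scaled$grid[, , , q] <- scaled$grid[, , , q] * c(2, 3, 4)[q]
  expect_equal(jacobian_at(scaled, 0.3, 0.3, 0.3)$det, 24)
  withr::with_seed(41, {
    sol <- rand_solid()
    for (rep in 1:10) {
      p <- runif(3)
      j <- jacobian_at(sol, p[1], p[2], p[3])
      expect_lt(max(abs(j$J %*% j$Jinv - diag(3))), 1e-10)
    }
  })
  flat <- cube
  flat$grid[, , , 3] <- 0   # collapse z: singular map
  expect_error(jacobian_at(flat, 0.5, 0.5, 0.5), "singular-mapping")
})

test_that("displacement interpolation matches direct summation and constants", {
  withr::with_seed(43, {
    sol <- rand_solid()
    d <- dim(sol$grid)[1:3]
    con <- displacement_field(sol, array(4, d), array(-2, d), array(0.5, d))
    expect_equal(displacement_at(con, 0.3, 0.7, 0.2), c(4, -2, 0.5))
    zero <- displacement_field(sol, array(0, d), array(0, d), array(0, d))
    expect_equal(displacement_at(zero, 0.1, 0.9, 0.5), c(0, 0, 0))
    fld <- random_field(sol)
    dsol <- sol; dsol$grid <- fld$d   # reuse the volume oracle on the d-grid
    for (rep in 1:10) {
      p <- runif(3)
      expect_equal(displacement_at(fld, p[1], p[2], p[3]),
                   direct_sum_volume(dsol, p[1], p[2], p[3]), tolerance = 1e-12)
    }
    expect_error(displacement_field(sol, array(0, d + 1L), array(0, d), array(0, d)),
                 "match the control grid")
  })
})

test_that("physical basis gradients transform through the Jacobian", {
  cube <- unit_cube_solid(n = 4)
  # J = I: physical equals parametric
  g <- basis_gradient_physical(cube, 1, 1, 1, 0.3, 0.4, 0.5)
  gpar <- c(basis_derivative(cube$knots_c, 1, 0.3) *
              basis_value(cube$knots_l, 1, 0.4) * basis_value(cube$knots_r, 1, 0.5),
            basis_value(cube$knots_c, 1, 0.3) *
              basis_derivative(cube$knots_l, 1, 0.4) * basis_value(cube$knots_r, 1, 0.5),
            basis_value(cube$knots_c, 1, 0.3) *
              basis_value(cube$knots_l, 1, 0.4) * basis_derivative(cube$knots_r, 1, 0.5))
  expect_equal(g, gpar, tolerance = 1e-12)
  # uniform scaling s: physical gradient = parametric / s
  s <- 2.5
  scaled <- cube; scaled$grid <- cube$grid * s
  expect_equal(basis_gradient_physical(scaled, 1, 1, 1, 0.3, 0.4, 0.5),
               gpar / s, tolerance = 1e-12)
  # gradients of a partition of unity sum to zero
  withr::with_seed(47, {
    sol <- rand_solid(c(5, 4, 4))
    p <- c(0.4, 0.6, 0.3)
    tot <- c(0, 0, 0)
    for (i in 0:(n_basis(sol$knots_c) - 1))
      for (j in 0:(n_basis(sol$knots_l) - 1))
        for (k in 0:(n_basis(sol$knots_r) - 1))
          tot <- tot + basis_gradient_physical(sol, i, j, k, p[1], p[2], p[3])
    expect_lt(max(abs(tot)), 1e-9)
  })
})

test_that("strain passes the kinematic patch tests", {
  withr::with_seed(53, {
    for (rep in 1:3) {
      sol <- rand_solid()
      d <- dim(sol$grid)[1:3]
      # rigid translation: zero strain everywhere
      trans <- displacement_field(sol, array(3, d), array(-1, d), array(7, d))
      g5 <- seq(0.05, 0.95, length.out = 5)
      for (t in g5) for (w in g5) for (u in g5)
        expect_lt(max(abs(strain_at(sol, trans, t, w, u)$voigt)), 1e-10)
      # uniform dilation alpha
      alpha <- 0.03
      dil <- affine_field(sol, diag(alpha, 3))
      for (p in list(c(0.2, 0.5, 0.7), c(0.8, 0.3, 0.5)))
        expect_equal(strain_at(sol, dil, p[1], p[2], p[3])$voigt,
                     c(alpha, alpha, alpha, 0, 0, 0),
                     tolerance = 1e-8, ignore_attr = TRUE)
      # simple shear u = beta * y
      beta <- 0.02
      A <- matrix(0, 3, 3); A[1, 2] <- beta
      sh <- affine_field(sol, A)
      for (p in list(c(0.4, 0.4, 0.4), c(0.6, 0.2, 0.9)))
        expect_equal(strain_at(sol, sh, p[1], p[2], p[3])$voigt,
                     c(0, 0, 0, beta, 0, 0),
                     tolerance = 1e-8, ignore_attr = TRUE)
    }
  })
})

test_that("strain matches the finite-difference chain-rule oracle", {
  withr::with_seed(59, {
    sol <- rand_solid()
    fld <- random_field(sol)
    for (rep in 1:50) {
      p <- runif(3, 0.02, 0.98)
      eps <- strain_at(sol, fld, p[1], p[2], p[3])$voigt
      oracle <- fd_strain(sol, fld, p[1], p[2], p[3])
      expect_lt(max(abs(eps - oracle)) / max(abs(eps), 1e-8), 1e-5)
    }
  })
})

test_that("stress is the elastic matrix applied to strain", {
  withr::with_seed(61, {
    sol <- rand_solid()
    d <- dim(sol$grid)[1:3]
    mat <- material_params()
    D <- elastic_matrix(mat)
    zero <- displacement_field(sol, array(0, d), array(0, d), array(0, d))
    expect_equal(stress_at(sol, zero, mat, 0.5, 0.5, 0.5)$voigt,
                 rep(0, 6), ignore_attr = TRUE)
    fld <- random_field(sol)
    for (rep in 1:10) {
      p <- runif(3)
      eps <- strain_at(sol, fld, p[1], p[2], p[3])$voigt
      sig <- stress_at(sol, fld, mat, p[1], p[2], p[3])$voigt
      expect_identical(unname(sig), unname(drop(D %*% eps)))  # bit-for-bit
    }
    # uniaxial at mu = 0: sigma = E * eps on the loaded axis only
    m0 <- material_params(E = 5, mu = 0)
    alpha <- 0.01
    A <- matrix(0, 3, 3); A[1, 1] <- alpha
    uni <- affine_field(sol, A)
    expect_equal(stress_at(sol, uni, m0, 0.5, 0.5, 0.5)$voigt,
                 c(5 * alpha, 0, 0, 0, 0, 0), tolerance = 1e-8,
                 ignore_attr = TRUE)
    # hydrostatic strain: closed-form bulk response E*alpha/(1-2mu)
    mh <- material_params(E = 11, mu = 0.3)
    hyd <- drop(elastic_matrix(mh) %*% c(alpha, alpha, alpha, 0, 0, 0))
    expect_equal(hyd[1], hyd[2])
    expect_equal(hyd[1], 11 * alpha / (1 - 2 * 0.3), tolerance = 1e-12)
    expect_equal(hyd[4:6], c(0, 0, 0))
  })
})

test_that("principal values are sorted eigenvalues with orthonormal directions", {
  expect_equal(principal_values(strain_state(c(3, 2, 1, 0, 0, 0)))$values, c(3, 2, 1))
  # pure engineering shear gamma_xy = 2g -> principal strains (g, 0, -g)
  g <- 0.01
  expect_equal(principal_values(strain_state(c(0, 0, 0, 2 * g, 0, 0)))$values,
               c(g, 0, -g), tolerance = 1e-12)
  # stress uses tau directly: tau_xy = s -> (s, 0, -s)
  expect_equal(principal_values(stress_state(c(0, 0, 0, 2, 0, 0)))$values,
               c(2, 0, -2))
  withr::with_seed(67, {
    for (rep in 1:20) {
      v <- rnorm(6, sd = 0.1)
      pv <- principal_values(strain_state(v))
      Tm <- matrix(c(v[1], v[4] / 2, v[6] / 2, v[4] / 2, v[2], v[5] / 2,
                     v[6] / 2, v[5] / 2, v[3]), 3, 3)
      # characteristic-polynomial root oracle
      roots <- sort(Re(polyroot(c(-det(Tm),
                                  (sum(diag(Tm))^2 - sum(Tm^2)) / 2,
                                  -sum(diag(Tm)), 1))), decreasing = TRUE)
      expect_equal(pv$values, roots, tolerance = 1e-10)
      expect_equal(t(pv$directions) %*% pv$directions, diag(3), tolerance = 1e-10)
      # invariance under rigid rotation of the tensor
      th <- runif(1, 0, pi)
      R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
      Tr <- R %*% Tm %*% t(R)
      vr <- c(diag(Tr), 2 * Tr[1, 2], 2 * Tr[2, 3], 2 * Tr[1, 3])
      expect_equal(principal_values(strain_state(vr))$values, pv$values,
                   tolerance = 1e-10)
    }
  })
})

test_that("phase differencing yields displacement fields with exact affine strain", {
  withr::with_seed(71, {
    sol <- rand_solid()
    # identical solids -> zero field
    z <- field_difference_displacements(sol, sol)
    expect_equal(max(abs(z$d)), 0)
    # translation -> constant field
    tr <- apply_deformation(sol, deformation_spec("translation", c(1, -2, 3)))
    f <- field_difference_displacements(sol, tr)
    expect_equal(displacement_at(f, 0.3, 0.3, 0.3), c(1, -2, 3), tolerance = 1e-12)
    # scaling about origin by 1 + alpha -> uniform strain alpha
    alpha <- 0.04
    sc <- apply_deformation(sol, deformation_spec("dilation", alpha))
    f2 <- field_difference_displacements(sol, sc)
    for (p in list(c(0.2, 0.4, 0.6), c(0.7, 0.7, 0.3)))
      expect_equal(strain_at(sol, f2, p[1], p[2], p[3])$voigt,
                   c(alpha, alpha, alpha, 0, 0, 0), tolerance = 1e-8,
                   ignore_attr = TRUE)
    # topology mismatch rejected
    other <- rand_solid(c(7, 5, 4))
    expect_error(field_difference_displacements(sol, other), "share control topology")
  })
})

test_that("field lattice sampling is consistent with pointwise evaluation", {
  withr::with_seed(73, {
    sol <- rand_solid(c(5, 4, 4))
    d <- dim(sol$grid)[1:3]
    mat <- material_params()
    zero <- displacement_field(sol, array(0, d), array(0, d), array(0, d))
    lat0 <- evaluate_field_grid(sol, zero, mat, c(2, 2, 2))
    expect_equal(nrow(lat0), 8)
    expect_true(all(abs(as.matrix(lat0[, 8:19])) == 0))
    fld <- random_field(sol, sd = 0.02)
    lat <- evaluate_field_grid(sol, fld, mat, c(3, 3, 2))
    row <- lat[7, ]   # some interior-ish lattice row
    eps <- strain_at(sol, fld, row$tc, row$tl, row$tr)$voigt
    expect_identical(unname(as.numeric(row[8:13])), unname(eps))
    expect_error(evaluate_field_grid(sol, fld, mat, c(1, 2, 2)), "resolution")
  })
})

test_that("volume quadrature reproduces analytic volumes and is order-stable", {
  cube <- unit_cube_solid()
  expect_equal(integrate_volume(cube, 4), 1, tolerance = 1e-12)
  scaled <- cube
  for (q in 1:3) scaled$grid[, , , q] <- scaled$grid[, , , q] * c(2, 3, 4)[q]
  expect_equal(integrate_volume(scaled, 4), 24, tolerance = 1e-10)
  sol <- annulus_solid()
  va <- pi * (30^2 - 20^2) * 50
  v4 <- integrate_volume(sol, 4)
  expect_lt(abs(v4 - va) / va, 0.01)
  v6 <- integrate_volume(sol, 6)
  expect_lt(abs(v6 - v4) / v4, 0.001)   # quadrature-order stability
  # negative Jacobian rejected
  flipped <- cube
  flipped$grid[, , , 1] <- -flipped$grid[, , , 1]
  expect_error(integrate_volume(flipped, 2), "negative det J")
})
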