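# Independent oracles and fixture builders. Everything here deliberately
# avoids the package's evaluation path: plain textbook recursion and brute
# force loops.

# Cox-de Boor by direct recursion, 0-based index i, degree k, knots tv.
# Half-open spans; closed at `right` for the final nonempty span.
cdb_recursive <- function(tv, i, k, t, right = tv[length(tv)]) {
  if (k == 0) {
    lo <- tv[i + 1]; hi <- tv[i + 2]
    inside <- (lo <= t && t < hi) || (t == right && hi == right && lo < hi)
    return(as.numeric(inside))
  }
  d1 <- tv[i + k + 1] - tv[i + 1]
  d2 <- tv[i + k + 2] - tv[i + 2]
  a <- if (d1 > 0) (t - tv[i + 1]) / d1 * cdb_recursive(tv, i, k - 1, t, right) else 0
  b <- if (d2 > 0) (tv[i + k + 2] - t) / d2 * cdb_recursive(tv, i + 1, k - 1, t, right) else 0
  a + b
}

# brute-force tensor-product evaluation with basis_value(), wrapping periodic
# control indices by hand
direct_sum_volume <- function(solid, t, w, u) {
  d <- dim(solid$grid)
  out <- numeric(3)
  nbc <- n_basis(solid$knots_c)
  for (i in seq_len(nbc)) {
    ic <- (i - 1) %% d[1] + 1
    Ni <- basis_value(solid$knots_c, i - 1, t)
    if (Ni == 0) next
    for (j in seq_len(n_basis(solid$knots_l))) {
      Nj <- basis_value(solid$knots_l, j - 1, w)
      if (Nj == 0) next
      for (k in seq_len(n_basis(solid$knots_r))) {
        Nk <- basis_value(solid$knots_r, k - 1, u)
        if (Nk == 0) next
        out <- out + Ni * Nj * Nk * solid$grid[ic, j, k, ]
      }
    }
  }
  out
}

direct_sum_surface <- function(surf, t, w) {
  d <- dim(surf$net)
  out <- numeric(3)
  for (i in seq_len(n_basis(surf$knots_t))) {
    ic <- (i - 1) %% d[1] + 1
    Ni <- basis_value(surf$knots_t, i - 1, t)
    for (j in seq_len(n_basis(surf$knots_w))) {
      out <- out + Ni * basis_value(surf$knots_w, j - 1, w) * surf$net[ic, j, ]
    }
  }
  out
}

# random open-clamped knot vector with nb basis functions on [0, 1]
rand_open_kv <- function(nb, degree) {
  n_int <- nb - degree - 1
  interior <- if (n_int > 0) sort(runif(n_int, 0.05, 0.95)) else numeric(0)
  knot_vector(c(rep(0, degree + 1), interior, rep(1, degree + 1)), degree, "open")
}

# well-shaped random solid: a jittered identity lattice (det J stays positive
# for small jitter), optionally scaled
rand_solid <- function(dims = c(6, 5, 4), degrees = c(3, 3, 3), jitter = 0.08,
                       scale = 1) {
  grid <- array(0, c(dims, 3))
  for (i in seq_len(dims[1])) for (j in seq_len(dims[2])) for (k in seq_len(dims[3])) {
    grid[i, j, k, ] <- c((i - 1) / (dims[1] - 1), (j - 1) / (dims[2] - 1),
                         (k - 1) / (dims[3] - 1)) +
      runif(3, -jitter, jitter) / max(dims)
  }
  grid <- grid * scale
  solid_model(grid,
              make_knot_vector(seq(0, 1, length.out = dims[1]), degrees[1], "uniform"),
              make_knot_vector(seq(0, 1, length.out = dims[2]), degrees[2], "uniform"),
              make_knot_vector(seq(0, 1, length.out = dims[3]), degrees[3], "uniform"))
}

# identity-lattice trilinear cube: V(t, w, u) = (t, w, u)
unit_cube_solid <- function(n = 2) {
  grid <- array(0, c(n, n, n, 3))
  g <- seq(0, 1, length.out = n)
  for (i in 1:n) for (j in 1:n) for (k in 1:n)
    grid[i, j, k, ] <- c(g[i], g[j], g[k])
  kv <- make_knot_vector(g, 1, "uniform")
  solid_model(grid, kv, kv, kv)
}

# displacement field interpolating the affine map d(x) = A x + b on any solid
affine_field <- function(solid, A, b = c(0, 0, 0)) {
  d <- dim(solid$grid)
  dx <- dy <- dz <- array(0, d[1:3])
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    v <- A %*% solid$grid[i, j, k, ] + b
    dx[i, j, k] <- v[1]; dy[i, j, k] <- v[2]; dz[i, j, k] <- v[3]
  }
  displacement_field(solid, dx, dy, dz)
}

random_field <- function(solid, sd = 0.05) {
  d <- dim(solid$grid)[1:3]
  displacement_field(solid, array(rnorm(prod(d), sd = sd), d),
                     array(rnorm(prod(d), sd = sd), d),
                     array(rnorm(prod(d), sd = sd), d))
}

# finite-difference chain-rule strain oracle: FD gradients of displacement_at
# and of the geometry, composed exactly as the continuum definition
fd_strain <- function(solid, field, tc, tl, tr, h = 1e-6) {
  fd <- function(f) {
    rbind((f(tc + h, tl, tr) - f(tc - h, tl, tr)) / (2 * h),
          (f(tc, tl + h, tr) - f(tc, tl - h, tr)) / (2 * h),
          (f(tc, tl, tr + h) - f(tc, tl, tr - h)) / (2 * h))
  }
  Gt <- fd(function(a, b, c) displacement_at(field, a, b, c))
  Jt <- fd(function(a, b, c) evaluate_volume(solid, a, b, c))  # rows: params
  Gx <- solve(Jt, Gt)   # Jt = J^T, so this is the transpose-inverse transform
  c(Gx[1, 1], Gx[2, 2], Gx[3, 3],
    Gx[2, 1] + Gx[1, 2], Gx[3, 2] + Gx[2, 3], Gx[3, 1] + Gx[1, 3])
}

# concentric-cylinder wall clouds (radius R, height h)
cylinder_cloud <- function(R, zs, pps = 32, wall = "inner") {
  ang <- 2 * pi * (0:(pps - 1)) / pps
  pts <- do.call(rbind, lapply(seq_along(zs), function(s)
    cbind(R * cos(ang), R * sin(ang), zs[s])))
  wall_cloud(pts, slice = rep(seq_along(zs) - 1L, each = pps), wall = wall)
}

annulus_solid <- function(Ri = 20, Ro = 30, h = 50, net = c(8, 4), layers = 5) {
  zs <- seq(0, h, length.out = 8)
  si <- fit_surface(cylinder_cloud(Ri, zs), net)
  so <- fit_surface(cylinder_cloud(Ro, zs, wall = "outer"), net,
                    knots_w = si$knots_w)
  fit_solid(sweep_hex_mesh(si, so, layers))
}
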