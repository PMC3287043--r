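#' Serialize a surface or solid model to JSON
#'
#' Stores degrees, knot values and form per direction, grid dimensions, the
#' coordinate-system tag, and the control points flattened in row-major
#' order (last control index varying fastest, one block per coordinate).
#' [load_model()] restores the object exactly (control values round-trip
#' bit-identically through the full-precision JSON encoding).
#'
#' @param model a [surface_model()] or [solid_model()].
#' @param path output `.json` path.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  if (inherits(model, "solid_model")) {
    d <- dim(model$grid)[1:3]
    kv <- list(c = model$knots_c, l = model$knots_l, r = model$knots_r)
    ctrl <- lapply(1:3, function(q) as.vector(aperm(model$grid[, , , q, drop = FALSE][, , , 1L],
                                                    c(3L, 2L, 1L))))
    obj <- list(type = "solid_model", coords = model$coords,
                degrees = model$degrees, dims = d,
                knots = lapply(kv, function(k) list(values = k$values,
                                                    degree = k$degree,
                                                    form = k$form)),
                control = stats::setNames(ctrl, c("x", "y", "z")))
  } else if (inherits(model, "surface_model")) {
    d <- dim(model$net)[1:2]
    kv <- list(t = model$knots_t, w = model$knots_w)
    ctrl <- lapply(1:3, function(q) as.vector(t(model$net[, , q])))
    obj <- list(type = "surface_model", coords = "cartesian",
                degrees = model$degrees, dims = d,
                knots = lapply(kv, function(k) list(values = k$values,
                                                    degree = k$degree,
                                                    form = k$form)),
                control = stats::setNames(ctrl, c("x", "y", "z")))
  } else stop("validation error: not a surface_model or solid_model")
  # 17 significant digits: doubles round-trip bit-identically
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' Load a surface or solid model from JSON
#'
#' @param path a `.json` file written by [save_model()].
#' @return the restored [surface_model()] or [solid_model()].
#' @export
load_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  mk_kv <- function(k) knot_vector(k$values, k$degree, k$form)
  if (identical(obj$type, "solid_model")) {
    d <- as.integer(obj$dims)
    grid <- array(0, c(d, 3L))
    for (q in 1:3) {
      v <- obj$control[[c("x", "y", "z")[q]]]
      grid[, , , q] <- aperm(array(v, d[c(3L, 2L, 1L)]), c(3L, 2L, 1L))
    }
    solid_model(grid, mk_kv(obj$knots$c), mk_kv(obj$knots$l), mk_kv(obj$knots$r),
                coords = obj$coords)
  } else if (identical(obj$type, "surface_model")) {
    d <- as.integer(obj$dims)
    net <- array(0, c(d, 3L))
    for (q in 1:3)
      net[, , q] <- t(matrix(obj$control[[c("x", "y", "z")[q]]], d[2L], d[1L]))
    surface_model(net, mk_kv(obj$knots$t), mk_kv(obj$knots$w))
  } else stop("schema error: unknown model type '", obj$type, "'")
}

#' Default pipeline configuration
#'
#' Degrees cubic in all three directions; 8 x 6 surface control nets; 4
#' radial layers; myocardial material E = 11 kPa, mu = 0.49; quadrature
#' order 4; a 16 x 12 x 4 field sampling lattice.
#'
#' @return named list of configuration values.
#' @export
default_config <- function() {
  list(degrees = c(3L, 3L, 3L),
       net = c(8L, 6L),
       radial_layers = 4L,
       material = list(E = 11, mu = 0.49),
       quadrature_order = 4L,
       resolution = c(16L, 12L, 4L),
       knot_method = "riesenfeld",
       seed = 1L)
}

#' Load a pipeline configuration from YAML
#'
#' Unknown keys and invalid values are rejected with the offending key
#' named; missing keys fall back to [default_config()].
#'
#' @param path YAML file path; `NULL` returns the defaults.
#' @return validated configuration list.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    user <- tryCatch(yaml::read_yaml(path), error = function(e)
      stop("schema error: cannot parse YAML config: ", conditionMessage(e)))
    if (!is.list(user)) stop("schema error: config must be a YAML mapping")
    bad <- setdiff(names(user), names(cfg))
    if (length(bad))
      stop("schema error: unknown config key '", bad[1L], "'")
    if ("material" %in% names(user)) {
      badm <- setdiff(names(user$material), c("E", "mu"))
      if (length(badm))
        stop("schema error: unknown config key 'material.", badm[1L], "'")
      user$material <- utils::modifyList(cfg$material, user$material)
    }
    cfg <- utils::modifyList(cfg, user)
  }
  validate_config(cfg)
}

#' @rdname load_config
#' @param cfg configuration list to validate.
#' @export
validate_config <- function(cfg) {
  chk <- function(ok, key, what)
    if (!ok) stop("schema error: config key '", key, "' ", what)
  cfg$degrees <- as.integer(cfg$degrees)
  chk(length(cfg$degrees) == 3L && all(cfg$degrees >= 1L), "degrees",
      "must be three integers >= 1")
  cfg$net <- as.integer(cfg$net)
  chk(length(cfg$net) == 2L && all(cfg$net >= cfg$degrees[1:2] + 1L), "net",
      "must be two integers, each > the matching degree")
  cfg$radial_layers <- as.integer(cfg$radial_layers)
  chk(cfg$radial_layers >= cfg$degrees[3L] + 1L, "radial_layers",
      "must be >= radial degree + 1")
  chk(is.numeric(cfg$material$E) && cfg$material$E > 0, "material.E",
      "must be > 0 (kPa)")
  chk(is.numeric(cfg$material$mu) && cfg$material$mu >= 0 && cfg$material$mu < 0.5,
      "material.mu", "must lie in [0, 0.5)")
  cfg$quadrature_order <- as.integer(cfg$quadrature_order)
  chk(cfg$quadrature_order >= 1L, "quadrature_order", "must be >= 1")
  cfg$resolution <- as.integer(cfg$resolution)
  chk(length(cfg$resolution) == 3L && all(cfg$resolution >= 2L), "resolution",
      "must be three integers >= 2")
  chk(cfg$knot_method %in% c("riesenfeld", "hartley_judd", "uniform"),
      "knot_method", "must be riesenfeld, hartley_judd or uniform")
  cfg
}

#' Fit one phase's wall clouds into a solid model
#'
#' Convenience wrapper: fit inner and outer surfaces (optionally with a
#' reference phase's parameterization and longitudinal knots), sweep the
#' hexahedral control mesh, and assemble the trivariate solid.
#'
#' @param inner,outer [wall_cloud()]s of one phase.
#' @param config configuration list, see [default_config()].
#' @param params_inner,params_outer optional reference-phase
#'   parameterizations (see [fit_surface()]).
#' @param knots_w optional shared longitudinal knot vector.
#' @return list with `solid`, `inner_surface`, `outer_surface`.
#' @export
build_phase_solid <- function(inner, outer, config = default_config(),
                              params_inner = NULL, params_outer = NULL,
                              knots_w = NULL) {
  si <- fit_surface(inner, config$net, config$degrees[1:2], params = params_inner,
                    knots_w = knots_w, knot_method = config$knot_method)
  so <- fit_surface(outer, config$net, config$degrees[1:2], params = params_outer,
                    knots_w = si$knots_w, knot_method = config$knot_method)
  mesh <- sweep_hex_mesh(si, so, config$radial_layers)
  list(solid = fit_solid(mesh, config$degrees[3L], config$knot_method),
       inner_surface = si, outer_surface = so)
}

#' Run the full strain/stress pipeline over a phase sequence
#'
#' For each cardiac phase, fits the wall surfaces (sharing the first phase's
#' parameterization and longitudinal knots so all solids have identical
#' control topology), sweeps the hexahedral mesh and builds the solid; for
#' each adjacent phase pair, forms the control-point displacement field and
#' samples strain, stress and principal fields over the parameter cube.
#' Optionally writes VTK, CSV and JSON summary files per pair.
#'
#' @param phases list (length >= 2) of phases, each a list with elements
#'   `inner` and `outer` ([wall_cloud()]s of consistent topology).
#' @param config configuration list, see [default_config()].
#' @param out_dir optional output directory; created if missing.
#' @return list with `solids`, `pairs` (per adjacent pair: `field`,
#'   `lattice`, `summary`), and `summary` (pipeline-level).
#' @export
run_pipeline <- function(phases, config = default_config(), out_dir = NULL) {
  config <- validate_config(config)
  if (!is.list(phases) || length(phases) < 2L)
    stop("validation error [phases]: need at least 2 phases of wall clouds")
  for (i in seq_along(phases)) {
    ph <- phases[[i]]
    if (!is.list(ph) || !inherits(ph$inner, "wall_cloud") ||
        !inherits(ph$outer, "wall_cloud"))
      stop("validation error [phases]: phase ", i,
           " must be a list with wall_cloud elements 'inner' and 'outer'")
    if (nrow(ph$inner$points) != nrow(phases[[1L]]$inner$points) ||
        nrow(ph$outer$points) != nrow(phases[[1L]]$outer$points))
      stop("validation error [phases]: phase ", i,
           " cloud topology differs from phase 1")
  }
  pin <- parameterize_cloud(phases[[1L]]$inner)
  pout <- parameterize_cloud(phases[[1L]]$outer)
  mat <- material_params(config$material$E, config$material$mu)

  # phase 1 establishes the longitudinal knots; later phases reuse them so
  # all solids share control topology
  stage <- "fit-surface/build-solid"
  built <- vector("list", length(phases))
  kw <- NULL
  for (i in seq_along(phases)) {
    built[[i]] <- tryCatch(
      build_phase_solid(phases[[i]]$inner, phases[[i]]$outer, config,
                        params_inner = pin, params_outer = pout, knots_w = kw),
      error = function(e) stop("stage ", stage, ", phase ", i, ": ",
                               conditionMessage(e), call. = FALSE))
    if (i == 1L) kw <- built[[1L]]$inner_surface$knots_w
  }
  solids <- lapply(built, `[[`, "solid")

  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)

  pairs <- vector("list", length(phases) - 1L)
  for (i in seq_len(length(phases) - 1L)) {
    field <- tryCatch(
      field_difference_displacements(solids[[i]], solids[[i + 1L]]),
      error = function(e) stop("stage displacement-field, pair ", i, ": ",
                               conditionMessage(e), call. = FALSE))
    lattice <- tryCatch(
      evaluate_field_grid(solids[[i]], field, mat, config$resolution),
      error = function(e) stop("stage analyze, pair ", i, ": ",
                               conditionMessage(e), call. = FALSE))
    comp <- c("eps_x", "eps_y", "eps_z", "gamma_xy", "gamma_yz", "gamma_xz",
              "sigma_x", "sigma_y", "sigma_z", "tau_xy", "tau_yz", "tau_xz")
    summ <- list(
      pair = c(i - 1L, i),
      detJ_range = range(lattice$detJ),
      fit_residuals = c(inner = attr(built[[i]]$inner_surface, "rms_residual"),
                        outer = attr(built[[i]]$outer_surface, "rms_residual")),
      components = lapply(stats::setNames(comp, comp), function(cn)
        list(min = min(lattice[[cn]]), max = max(lattice[[cn]]),
             mean = mean(lattice[[cn]]))))
    if (!is.null(out_dir)) {
      write_vtk_grid(lattice, file.path(out_dir, sprintf("fields_pair%02d.vtk", i)))
      utils::write.csv(lattice, file.path(out_dir, sprintf("fields_pair%02d.csv", i)),
                       row.names = FALSE)
      jsonlite::write_json(summ, file.path(out_dir, sprintf("summary_pair%02d.json", i)),
                           auto_unbox = TRUE, digits = NA)
    }
    pairs[[i]] <- list(field = field, lattice = lattice, summary = summ)
  }
  if (!is.null(out_dir))
    for (i in seq_along(solids))
      save_model(solids[[i]], file.path(out_dir, sprintf("solid_phase%02d.json", i - 1L)))
  list(solids = solids, pairs = pairs,
       summary = list(n_phases = length(phases),
                      config = config,
                      fit_residuals = vapply(built, function(b)
                        attr(b$inner_surface, "rms_residual"), numeric(1))))
}

#' Write a sampled field lattice as a legacy VTK structured grid
#'
#' ASCII legacy VTK with point data arrays: `displacement` is not stored (it
#' is recoverable from the phase solids); per-point arrays are `strain6`,
#' `stress6`, `principal_strain`, `principal_stress`, `epsx`, `sigx` and
#' `detJ`. Point ordering matches [evaluate_field_grid()] (circumferential
#' fastest).
#'
#' @param lattice data frame from [evaluate_field_grid()] (must carry its
#'   `resolution` attribute).
#' @param path output `.vtk` path.
#' @return `path`, invisibly.
#' @export
write_vtk_grid <- function(lattice, path) {
  res <- attr(lattice, "resolution")
  if (is.null(res))
    stop("validation error: lattice lacks a resolution attribute")
  n <- nrow(lattice)
  fmt <- function(m) apply(format(m, digits = 9, trim = TRUE, scientific = TRUE),
                           1L, paste, collapse = " ")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "lvspline strain/stress field lattice",
               "ASCII",
               "DATASET STRUCTURED_GRID",
               paste("DIMENSIONS", res[1L], res[2L], res[3L]),
               paste("POINTS", n, "double")), con)
  writeLines(fmt(as.matrix(lattice[, c("x", "y", "z")])), con)
  writeLines(paste("POINT_DATA", n), con)
  arr <- function(name, cols) {
    writeLines(c(paste("FIELD", name, 1),
                 paste(name, length(cols), n, "double")), con)
    writeLines(fmt(as.matrix(lattice[, cols, drop = FALSE])), con)
  }
  arr("strain6", c("eps_x", "eps_y", "eps_z", "gamma_xy", "gamma_yz", "gamma_xz"))
  arr("stress6", c("sigma_x", "sigma_y", "sigma_z", "tau_xy", "tau_yz", "tau_xz"))
  arr("principal_strain", c("e1", "e2", "e3"))
  arr("principal_stress", c("s1", "s2", "s3"))
  writeLines(c("SCALARS epsx double 1", "LOOKUP_TABLE default"), con)
  writeLines(format(lattice$eps_x, digits = 9, trim = TRUE, scientific = TRUE), con)
  writeLines(c("SCALARS sigx double 1", "LOOKUP_TABLE default"), con)
  writeLines(format(lattice$sigma_x, digits = 9, trim = TRUE, scientific = TRUE), con)
  writeLines(c("SCALARS detJ double 1", "LOOKUP_TABLE default"), con)
  writeLines(format(lattice$detJ, digits = 9, trim = TRUE, scientific = TRUE), con)
  invisible(path)
}
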