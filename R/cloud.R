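#' Slice-stacked wall point cloud
#'
#' Container for segmented wall contour points of one cardiac phase: 3-D
#' Cartesian points grouped into short-axis slices, each slice an ordered
#' contour ring, tagged as inner (endocardial) or outer (epicardial) wall.
#'
#' @param points numeric `n x 3` matrix (mm).
#' @param slice integer slice index per point; slices are ordered along z.
#' @param ring integer position around the contour within each slice
#'   (`0..points_in_slice-1`); if `NULL`, a nearest-angle ordering about the
#'   slice centroid is assigned.
#' @param wall `"inner"` or `"outer"`.
#' @param phase cardiac-phase index (integer).
#' @return object of class `wall_cloud`.
#' @export
wall_cloud <- function(points, slice, ring = NULL, wall = c("inner", "outer"),
                       phase = 0L) {
  wall <- match.arg(wall)
  points <- as.matrix(points)
  if (ncol(points) != 3L || any(!is.finite(points)))
    stop("validation error: points must be a finite n x 3 matrix")
  slice <- as.integer(slice)
  if (length(slice) != nrow(points))
    stop("validation error: slice index length must match point count")
  tab <- table(slice)
  if (any(tab < 4L))
    stop("validation error: every slice needs at least 4 points")
  if (is.null(ring)) {
    ring <- integer(nrow(points))
    for (s in unique(slice)) {
      idx <- which(slice == s)
      ctr <- colMeans(points[idx, , drop = FALSE])
      th <- atan2(points[idx, 2L] - ctr[2L], points[idx, 1L] - ctr[1L]) %% (2 * pi)
      ring[idx] <- order(order(th)) - 1L
    }
  } else {
    ring <- as.integer(ring)
    for (s in unique(slice)) {
      r <- sort(ring[slice == s])
      if (!identical(r, seq_along(r) - 1L))
        stop("validation error: ring_order must be a permutation of 0..n-1 within slice ", s)
    }
  }
  structure(list(points = points, slice = slice, ring = ring,
                 wall = wall, phase = as.integer(phase)),
            class = "wall_cloud")
}

#' @export
print.wall_cloud <- function(x, ...) {
  cat(sprintf("<wall_cloud> %s wall, phase %d: %d points in %d slices\n",
              x$wall, x$phase, nrow(x$points), length(unique(x$slice))))
  invisible(x)
}

#' Surface parameters for a wall point cloud
#'
#' Assigns each point a circumferential parameter `t` from its azimuth about
#' the z-axis (`theta / 2*pi`, in `[0, 1)`) and a longitudinal parameter `w`
#' shared by all points of a slice, from normalized chord length along the
#' z-ordered slice centroids.
#'
#' @param cloud a [wall_cloud()].
#' @return data frame with columns `t`, `w` (one row per point, cloud order).
#' @export
parameterize_cloud <- function(cloud) {
  stopifnot(inherits(cloud, "wall_cloud"))
  pts <- cloud$points
  slices <- sort(unique(cloud$slice))
  ctrs <- t(vapply(slices, function(s) {
    colMeans(pts[cloud$slice == s, , drop = FALSE])
  }, numeric(3)))
  ord <- order(ctrs[, 3L])
  slices <- slices[ord]; ctrs <- ctrs[ord, , drop = FALSE]
  for (s in slices) {
    sub <- pts[cloud$slice == s, , drop = FALSE]
    if (max(apply(sub, 2L, function(v) diff(range(v)))) < 1e-9)
      stop("validation error: degenerate slice ", s, " (all points coincident)")
  }
  chord <- c(0, cumsum(sqrt(rowSums(diff(ctrs)^2))))
  if (chord[length(chord)] <= 0)
    stop("validation error: slices are coincident along z")
  wv <- chord / chord[length(chord)]
  w <- wv[match(cloud$slice, slices)]
  th <- to_cylindrical(pts)[, 2L]
  data.frame(t = th / (2 * pi), w = w)
}

#' Read a wall point cloud from CSV or XYZ text
#'
#' CSV files need a header with columns `x,y,z,slice,ring,wall,phase`
#' (`ring`, `wall`, `phase` optional). Plain whitespace-separated XYZ files
#' (three columns, no header) are accepted with slices inferred by clustering
#' the z coordinates at gaps larger than `z_gap`.
#'
#' @param path file path.
#' @param wall wall tag used when the file does not carry one.
#' @param z_gap minimum z separation (mm) between inferred slices for XYZ
#'   input.
#' @return a [wall_cloud()].
#' @export
read_wall_cloud <- function(path, wall = "inner", z_gap = 1) {
  first <- readLines(path, n = 1L)
  if (grepl("[A-Za-z]", first)) {
    df <- utils::read.csv(path)
    need <- c("x", "y", "z", "slice")
    if (!all(need %in% names(df)))
      stop("validation error: cloud CSV must have columns x,y,z,slice")
    wall_cloud(as.matrix(df[, c("x", "y", "z")]),
               slice = df$slice,
               ring = if ("ring" %in% names(df)) df$ring else NULL,
               wall = if ("wall" %in% names(df)) as.character(df$wall[1L]) else wall,
               phase = if ("phase" %in% names(df)) df$phase[1L] else 0L)
  } else {
    m <- as.matrix(utils::read.table(path))
    if (ncol(m) != 3L) stop("validation error: XYZ file must have 3 columns")
    z <- m[, 3L]
    o <- order(z)
    brk <- c(0L, which(diff(z[o]) > z_gap), length(z))
    slice <- integer(length(z))
    for (s in seq_len(length(brk) - 1L))
      slice[o[(brk[s] + 1L):brk[s + 1L]]] <- s - 1L
    wall_cloud(m, slice = slice, wall = wall)
  }
}

#' Write a wall point cloud as CSV
#'
#' Columns `x,y,z,slice,ring,wall,phase`, the same dialect
#' [read_wall_cloud()] accepts.
#'
#' @param cloud a [wall_cloud()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_wall_cloud <- function(cloud, path) {
  stopifnot(inherits(cloud, "wall_cloud"))
  df <- data.frame(x = cloud$points[, 1L], y = cloud$points[, 2L],
                   z = cloud$points[, 3L], slice = cloud$slice,
                   ring = cloud$ring, wall = cloud$wall, phase = cloud$phase)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
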