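#' Knot vectors for B-spline bases
#'
#' A knot vector is a nondecreasing parameter sequence `values` together with
#' a polynomial `degree` and a `form`. The open-clamped form repeats the first
#' and last knot exactly `degree + 1` times so the spline interpolates its end
#' control points; the periodic form carries uniform padding of `degree` knots
#' on either side of the unit interval so that evaluation wraps smoothly on
#' a closed (circumferential) direction.
#'
#' For a degree-`k` vector of length `n + k + 2` there are `n + 1` basis
#' functions, indexed `0..n`.
#'
#' @param values numeric, nondecreasing knot sequence.
#' @param degree nonnegative integer polynomial degree.
#' @param form `"open"` (clamped) or `"periodic"`.
#' @return An object of class `knot_vector`.
#' @export
knot_vector <- function(values, degree, form = c("open", "periodic")) {
  form <- match.arg(form)
  values <- as.numeric(values)
  if (anyNA(values) || any(!is.finite(values)))
    stop("knot vector validation error: non-finite knot values")
  if (is.unsorted(values))
    stop("knot vector validation error: knot values must be nondecreasing")
  degree <- as.integer(degree)
  if (degree < 0) stop("knot vector validation error: degree must be >= 0")
  nb <- length(values) - degree - 1L
  if (nb < 1L)
    stop("knot vector validation error: too few knots for degree ", degree)
  if (form == "open") {
    k1 <- degree + 1L
    if (any(values[seq_len(k1)] != values[1L]) ||
        any(values[length(values) - seq_len(k1) + 1L] != values[length(values)]))
      stop("knot vector validation error: open-clamped form must repeat end knots degree+1 times")
  }
  structure(list(values = values, degree = degree, form = form),
            class = "knot_vector")
}

#' @export
print.knot_vector <- function(x, ...) {
  cat(sprintf("<knot_vector> degree %d, %s, %d basis functions\n",
              x$degree, x$form, n_basis(x)))
  cat("  knots:", paste(signif(x$values, 4), collapse = " "), "\n")
  invisible(x)
}

#' Number of basis functions carried by a knot vector
#' @param kv a [knot_vector()].
#' @return integer count of basis functions (`n + 1`).
#' @export
n_basis <- function(kv) length(kv$values) - kv$degree - 1L

#' Evaluation domain of a knot vector
#' @param kv a [knot_vector()].
#' @return numeric length-2 vector `[t_k, t_{n+1}]`.
#' @export
kv_domain <- function(kv) {
  nb <- n_basis(kv)
  c(kv$values[kv$degree + 1L], kv$values[nb + 1L])
}

#' Uniform periodic knot vector on the unit interval
#'
#' Constructs the knot vector used for a closed circumferential direction with
#' `n_unique` independent control columns: uniform knots `(j - degree)/n_unique`
#' for `j = 0..n_unique + 2*degree`. Evaluation on `[0, 1)` together with
#' control-point wrapping (the first `degree` control columns repeated) gives a
#' C^(degree-1)-continuous closed curve.
#'
#' @param n_unique number of unique control points around the loop
#'   (must exceed the degree).
#' @param degree polynomial degree.
#' @return a periodic [knot_vector()] with `n_unique + degree` basis functions.
#' @export
periodic_knot_vector <- function(n_unique, degree) {
  n_unique <- as.integer(n_unique)
  degree <- as.integer(degree)
  if (n_unique <= degree)
    stop("knot vector validation error: periodic direction needs more than degree unique control points")
  j <- 0:(n_unique + 2L * degree)
  knot_vector((j - degree) / n_unique, degree, form = "periodic")
}

#' Build an open-clamped knot vector from data parameters
#'
#' Interior knots are placed from an ordered list of data-site parameters,
#' which is first normalized to `[0, 1]`. Methods:
#' \describe{
#'   \item{riesenfeld}{knot averaging: interior knot `j` is the mean of
#'     parameters `j+1 .. j+degree` (1-based).}
#'   \item{hartley_judd}{chord-length-weighted placement: knot spacing
#'     proportional to sums of `degree` consecutive parameter increments.}
#'   \item{uniform}{equally spaced interior knots (synthetic fixtures).}
#' }
#' The number of basis functions equals `length(params)`.
#'
#' @param params strictly increasing parameter values (after normalization).
#' @param degree polynomial degree.
#' @param method one of `"riesenfeld"`, `"hartley_judd"`, `"uniform"`.
#' @return an open-clamped [knot_vector()] on `[0, 1]`.
#' @export
make_knot_vector <- function(params, degree,
                             method = c("riesenfeld", "hartley_judd", "uniform")) {
  method <- match.arg(method)
  degree <- as.integer(degree)
  params <- as.numeric(params)
  np <- length(params)
  if (np < degree + 1L)
    stop("knot vector validation error: need at least degree+1 parameters, got ", np)
  u <- (params - params[1L]) / (params[np] - params[1L])
  if (any(diff(u) <= 0))
    stop("knot vector validation error: parameters must be strictly increasing")
  n_int <- np - degree - 1L
  interior <- numeric(0)
  if (n_int > 0L) {
    interior <- switch(method,
      riesenfeld = vapply(seq_len(n_int), function(j) {
        mean(u[(j + 1L):(j + degree)])
      }, numeric(1)),
      hartley_judd = {
        ci <- diff(u)                       # np - 1 increments
        w <- vapply(seq_len(n_int + 1L), function(s) {
          sum(ci[s:(s + degree - 1L)])
        }, numeric(1))
        (cumsum(w) / sum(w))[seq_len(n_int)]
      },
      uniform = seq_len(n_int) / (n_int + 1L)
    )
  }
  knot_vector(c(rep(0, degree + 1L), interior, rep(1, degree + 1L)),
              degree, form = "open")
}

# wrap a parameter into the periodic unit domain
.wrap_param <- function(t) t - floor(t)

# all basis values (or first derivatives) at scalar t; returns length n_basis
.basis_row1 <- function(kv, t, deriv = 0L) {
  tv <- kv$values
  k <- kv$degree
  nb <- length(tv) - k - 1L
  dom <- c(tv[k + 1L], tv[nb + 1L])
  if (kv$form == "periodic") {
    t <- .wrap_param(t)
  } else if (t < dom[1L] || t > dom[2L]) {
    stop(sprintf("domain error: parameter t=%g outside evaluation span [%g, %g]",
                 t, dom[1L], dom[2L]))
  }
  right <- dom[2L]

  lower_to <- if (deriv > 0L) k - 1L else k
  n0 <- nb + k
  lo <- tv[seq_len(n0)]
  hi <- tv[2L:(n0 + 1L)]
  N <- as.numeric(lo <= t & t < hi)
  if (!any(N > 0) && t == right) {
    # closed-at-right convention: last nonempty span ending at the domain end
    N <- as.numeric(lo <= t & t <= hi & lo < hi & hi == right)
    if (sum(N) > 1) {                       # keep only the last such span
      last <- max(which(N > 0)); N[] <- 0; N[last] <- 1
    }
  }
  d <- 0L
  while (d < lower_to) {
    d <- d + 1L
    m <- n0 - d
    i <- seq_len(m)
    den1 <- tv[i + d] - tv[i]
    den2 <- tv[i + d + 1L] - tv[i + 1L]
    a <- ifelse(den1 > 0, (t - tv[i]) / den1, 0)     # 0/0 := 0
    b <- ifelse(den2 > 0, (tv[i + d + 1L] - t) / den2, 0)
    N <- a * N[i] + b * N[i + 1L]
  }
  if (deriv == 0L) return(N)
  # derivative via two-term difference of degree k-1 bases; N has length nb + 1
  i <- seq_len(nb)
  den1 <- tv[i + k] - tv[i]
  den2 <- tv[i + k + 1L] - tv[i + 1L]
  t1 <- ifelse(den1 > 0, N[i] / den1, 0)
  t2 <- ifelse(den2 > 0, N[i + 1L] / den2, 0)
  k * (t1 - t2)
}

#' All B-spline basis values or derivatives at given parameters
#'
#' Evaluates every basis function carried by `kv` at each element of `t`.
#' Half-open spans are closed at the global right endpoint so the domain
#' boundary is evaluable; `0/0` intervals contribute 0. Periodic knot vectors
#' wrap `t` into `[0, 1)`.
#'
#' @param kv a [knot_vector()].
#' @param t numeric parameters.
#' @param deriv 0 for values, 1 for first derivatives (degree must be >= 1).
#' @return matrix `length(t) x n_basis(kv)`.
#' @export
basis_row <- function(kv, t, deriv = 0L) {
  stopifnot(inherits(kv, "knot_vector"))
  deriv <- as.integer(deriv)
  if (deriv < 0L || deriv > 1L) stop("deriv must be 0 or 1")
  if (deriv == 1L && kv$degree < 1L)
    stop("domain error: derivative requires degree >= 1")
  out <- t(vapply(as.numeric(t), function(ti) .basis_row1(kv, ti, deriv),
                  numeric(n_basis(kv))))
  out
}

#' Single B-spline basis function value \eqn{N_{i,k}(t)}
#'
#' @param kv a [knot_vector()].
#' @param i 0-based basis index in `0..n`.
#' @param t scalar parameter inside the evaluation span.
#' @return scalar basis value, nonnegative.
#' @export
basis_value <- function(kv, i, t) {
  i <- as.integer(i)
  if (i < 0L || i >= n_basis(kv))
    stop("domain error: basis index i=", i, " outside 0..", n_basis(kv) - 1L)
  .basis_row1(kv, t, 0L)[i + 1L]
}

#' Single B-spline basis derivative \eqn{dN_{i,k}/dt}
#'
#' Uses the standard two-term difference of degree `k-1` bases,
#' \eqn{k[N_{i,k-1}/(t_{i+k}-t_i) - N_{i+1,k-1}/(t_{i+k+1}-t_{i+1})]},
#' with vanishing denominators contributing 0.
#'
#' @inheritParams basis_value
#' @return scalar derivative value.
#' @export
basis_derivative <- function(kv, i, t) {
  i <- as.integer(i)
  if (i < 0L || i >= n_basis(kv))
    stop("domain error: basis index i=", i, " outside 0..", n_basis(kv) - 1L)
  .basis_row1(kv, t, 1L)[i + 1L]
}

# collapse a wrapped periodic basis row (length n_unique + degree) onto the
# n_unique unique control columns
.collapse_periodic <- function(b, n_unique, degree) {
  if (degree > 0L) {
    idx <- n_unique + seq_len(degree)
    b[seq_len(degree)] <- b[seq_len(degree)] + b[idx]
  }
  b[seq_len(n_unique)]
}

# basis row matched to a control-dimension of size nctrl: collapses periodic
# wrapped bases so the result always has length nctrl
.ctrl_basis <- function(kv, t, nctrl, deriv = 0L) {
  b <- .basis_row1(kv, t, deriv)
  if (kv$form == "periodic") b <- .collapse_periodic(b, nctrl, kv$degree)
  if (length(b) != nctrl)
    stop("validation error: knot vector carries ", length(b),
         " basis functions for ", nctrl, " control points")
  b
}
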