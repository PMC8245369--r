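# Chord-length parameter of an ordered point matrix: cumulative Euclidean
# distance along the polyline, starting at 0.
chord_param <- function(pts) {
  d <- sqrt(rowSums((pts[-1, , drop = FALSE] - pts[-nrow(pts), , drop = FALSE])^2))
  c(0, cumsum(d))
}

#' Gaussian denoising of a tracked point sequence
#'
#' Replaces each point by a Gaussian-weighted average of its neighbours,
#' with weights computed over the chord-length parameter (physical
#' distance along the polyline), so unevenly spaced manual tracks are
#' handled consistently. The "window" is interpreted as the truncation
#' width W of the kernel: standard deviation sigma = W/4, weights
#' truncated at +/- W/2 and renormalized at the track ends. W = 4 sigma
#' captures about 95% of the kernel mass; with this convention a 100 um
#' window barely smooths typical manual tracks, 1000 um removes tracking
#' jitter while preserving organ shape, and 10000 um collapses the track
#' toward its mean (over-smoothing).
#'
#' @param points matrix of ordered 3D points (rows), micrometres.
#' @param window_um kernel truncation width W in micrometres (> 0).
#' @return matrix of the same dimensions with smoothed coordinates.
#' @export
gaussian_smooth <- function(points, window_um) {
  points <- as.matrix(points)
  if (nrow(points) < 2) stop("at least 2 points are required", call. = FALSE)
  if (!is.finite(window_um) || window_um <= 0) {
    stop("window_um must be positive", call. = FALSE)
  }
  t <- chord_param(points)
  sigma <- window_um / 4
  half <- window_um / 2
  out <- points
  for (i in seq_along(t)) {
    d <- t - t[i]
    keep <- abs(d) <= half
    w <- exp(-d[keep]^2 / (2 * sigma^2))
    out[i, ] <- colSums(points[keep, , drop = FALSE] * w) / sum(w)
  }
  out
}

#' Fit a smooth differentiable curve through tracked points
#'
#' Converts an ordered 3D point sequence into a continuous curve with an
#' analytic first derivative, fitting each coordinate against a common
#' scalar parameter. Three methods are provided:
#' \describe{
#'   \item{`cubic`}{natural cubic spline interpolation through every point
#'     (continuous first and second derivatives; zero knot residual).
#'     This is the recommended method: unlike the global fits below it
#'     imposes no functional form on the organ shape.}
#'   \item{`poly9`}{per-coordinate degree-9 least-squares polynomial. A
#'     global fit with few degrees of freedom; included because its
#'     characteristic misfit on wavy organ outlines is a useful negative
#'     control.}
#'   \item{`gauss8`}{per-coordinate least-squares sum of 8 Gaussian bumps
#'     plus a constant offset, fitted by Levenberg--Marquardt nonlinear
#'     least squares from deterministic starts (centers evenly spread over
#'     the domain, widths = domain/16, amplitudes from a linear
#'     warm start). Same caveat as `poly9`.}
#' }
#'
#' @param points matrix of ordered 3D points (rows).
#' @param method one of `"cubic"`, `"poly9"`, `"gauss8"`.
#' @param parameterization `"chord_length"` (default; cumulative distance
#'   along the polyline, works for any orientation) or `"axis_z"` (the raw
#'   z coordinate; requires strictly monotone z and only makes sense when
#'   the organ's long axis is nearly parallel to z).
#' @return An object of class `smooth_curve`: list with `evaluate(u)` and
#'   `derivative(u)` (both mapping a parameter vector to an n x 3 matrix),
#'   `domain`, `parameterization`, `method`, and the knot parameters/points.
#' @export
fit_curve <- function(points, method = c("cubic", "poly9", "gauss8"),
                      parameterization = c("chord_length", "axis_z")) {
  points <- as.matrix(points)
  method <- match.arg(method)
  parameterization <- match.arg(parameterization)
  n <- nrow(points)
  if (n < 4) stop("at least 4 points are required", call. = FALSE)
  if (parameterization == "chord_length") {
    u <- chord_param(points)
  } else {
    u <- points[, 3]
    if (any(diff(u) <= 0)) {
      stop("axis_z parameterization requires strictly increasing z", call. = FALSE)
    }
  }

  fit1 <- switch(method,
    cubic = lapply(1:3, function(j) {
      f <- stats::splinefun(u, points[, j], method = "natural")
      list(value = f, deriv = function(x) f(x, deriv = 1))
    }),
    poly9 = lapply(1:3, function(j) fit_poly9(u, points[, j])),
    gauss8 = lapply(1:3, function(j) fit_gauss8(u, points[, j]))
  )
  evaluate <- function(uu) {
    m <- vapply(fit1, function(f) f$value(uu), numeric(length(uu)))
    matrix(m, ncol = 3, dimnames = list(NULL, c("x", "y", "z")))
  }
  derivative <- function(uu) {
    m <- vapply(fit1, function(f) f$deriv(uu), numeric(length(uu)))
    matrix(m, ncol = 3, dimnames = list(NULL, c("x", "y", "z")))
  }
  structure(list(evaluate = evaluate, derivative = derivative,
                 domain = range(u), parameterization = parameterization,
                 method = method, knots = u, points = points),
            class = "smooth_curve")
}

#' @export
print.smooth_curve <- function(x, ...) {
  cat(sprintf("Smooth 3D curve: %s fit, %s parameterization, %d knots, domain [%.6g, %.6g]\n",
              x$method, x$parameterization, length(x$knots),
              x$domain[1], x$domain[2]))
  invisible(x)
}

# Degree-9 least-squares polynomial on a rescaled parameter for conditioning.
fit_poly9 <- function(u, y) {
  mid <- mean(range(u)); scl <- diff(range(u)) / 2
  t <- (u - mid) / scl
  X <- outer(t, 0:9, `^`)
  beta <- stats::lm.fit(X, y)$coefficients
  beta[is.na(beta)] <- 0
  dbeta <- beta[-1] * (1:9)
  list(
    value = function(uu) {
      tt <- (uu - mid) / scl
      drop(outer(tt, 0:9, `^`) %*% beta)
    },
    deriv = function(uu) {
      tt <- (uu - mid) / scl
      drop(outer(tt, 0:8, `^`) %*% dbeta) / scl
    }
  )
}

# Sum of 8 Gaussian bumps + offset, per coordinate. Deterministic start:
# centers at 8 evenly spaced positions across the domain, common width
# domain/16, amplitudes from a linear least-squares warm start.
fit_gauss8 <- function(u, y) {
  rng <- range(u); span <- diff(rng)
  mu0 <- seq(rng[1] + span / 16, rng[2] - span / 16, length.out = 8)
  w0 <- rep(span / 16, 8)
  basis <- function(mu, w) {
    vapply(1:8, function(k) exp(-(u - mu[k])^2 / (2 * w[k]^2)), numeric(length(u)))
  }
  B <- cbind(1, basis(mu0, w0))
  amp0 <- stats::lm.fit(B, y)$coefficients
  amp0[is.na(amp0)] <- 0
  start <- c(c0 = unname(amp0[1]), a = unname(amp0[-1]), mu = mu0, w = w0)
  model <- function(p, uu) {
    c0 <- p[1]; a <- p[2:9]; mu <- p[10:17]; w <- p[18:25]
    v <- rep(c0, length(uu))
    for (k in 1:8) v <- v + a[k] * exp(-(uu - mu[k])^2 / (2 * w[k]^2))
    v
  }
  fit <- tryCatch(
    minpack.lm::nls.lm(par = start,
                       fn = function(p) y - model(p, u),
                       control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop(sprintf("gauss8 fit failed to converge: %s",
                                     conditionMessage(e)), call. = FALSE)
  )
  p <- fit$par
  list(
    value = function(uu) model(p, uu),
    deriv = function(uu) {
      a <- p[2:9]; mu <- p[10:17]; w <- p[18:25]
      v <- numeric(length(uu))
      for (k in 1:8) {
        v <- v - a[k] * (uu - mu[k]) / w[k]^2 * exp(-(uu - mu[k])^2 / (2 * w[k]^2))
      }
      v
    }
  )
}

#' Arc length along a smooth curve
#'
#' Integrates the norm of the curve derivative between two parameter
#' values by adaptive quadrature. This is the curved distance along the
#' organ; measured from the blade--petiole junction end it is the
#' position-along-the-organ coordinate s.
#'
#' @param curve a [fit_curve()] result.
#' @param a,b parameter values within the curve domain, `a <= b`
#'   (defaults: the whole domain).
#' @return arc length in micrometres.
#' @export
arc_length <- function(curve, a = curve$domain[1], b = curve$domain[2]) {
  stopifnot(inherits(curve, "smooth_curve"))
  eps <- 1e-9 * max(1, diff(curve$domain))
  if (a < curve$domain[1] - eps || b > curve$domain[2] + eps || a > b + eps) {
    stop("arc_length parameters outside the curve domain", call. = FALSE)
  }
  if (b - a <= 0) return(0)
  speed <- function(uu) sqrt(rowSums(curve$derivative(uu)^2))
  # integrate over knot-aligned panels: the spline speed is smooth inside
  # each panel, which keeps the adaptive quadrature honest at knots
  brk <- unique(c(a, curve$knots[curve$knots > a & curve$knots < b], b))
  total <- 0
  for (i in seq_len(length(brk) - 1)) {
    total <- total + stats::integrate(speed, brk[i], brk[i + 1],
                                      rel.tol = 1e-10, abs.tol = 1e-10,
                                      subdivisions = 200L)$value
  }
  total
}

#' Resample a curve at uniform arc-length steps
#'
#' Finds the curve parameters u(s) at s = 0, ds, 2 ds, ... up to the total
#' arc length by monotone root-finding on the arc-length function, so
#' downstream finite differences can be taken on a uniform s grid.
#'
#' @param curve a [fit_curve()] result.
#' @param ds_um step in micrometres (> 0 and no larger than the total
#'   arc length).
#' @return data frame with columns `s` (achieved arc length from the
#'   domain start, within 1e-3 um of the requested multiples of `ds_um`)
#'   and `u` (curve parameter).
#' @export
resample_uniform <- function(curve, ds_um) {
  stopifnot(inherits(curve, "smooth_curve"))
  if (!is.finite(ds_um) || ds_um <= 0) {
    stop("ds_um must be positive", call. = FALSE)
  }
  total <- arc_length(curve)
  if (ds_um > total) {
    stop(sprintf("ds_um (%g) exceeds the total arc length (%g um)", ds_um, total),
         call. = FALSE)
  }
  s_grid <- seq(0, total, by = ds_um)
  u <- numeric(length(s_grid))
  u[1] <- curve$domain[1]
  for (k in seq_along(s_grid)[-1]) {
    lo <- u[k - 1]
    f <- function(uu) arc_length(curve, lo, uu) - ds_um
    # arc length grows at least as fast as straight-line distance, so the
    # bracket [lo, hi] with hi stepped forward until f(hi) >= 0 is safe
    hi <- min(lo + ds_um, curve$domain[2])
    while (f(hi) < 0 && hi < curve$domain[2]) {
      hi <- min(hi + ds_um, curve$domain[2])
    }
    u[k] <- stats::uniroot(f, c(lo, hi), tol = 1e-7 * max(1, ds_um))$root
  }
  data.frame(s = s_grid, u = u)
}
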