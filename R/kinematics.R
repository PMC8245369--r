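unit3 <- function(v) v / sqrt(sum(v^2))

cross3 <- function(a, b) {
  unname(c(a[2] * b[3] - a[3] * b[2],
           a[3] * b[1] - a[1] * b[3],
           a[1] * b[2] - a[2] * b[1]))
}

# Rowwise cross product for n x 3 matrices.
cross3_rows <- function(A, B) {
  cbind(A[, 2] * B[, 3] - A[, 3] * B[, 2],
        A[, 3] * B[, 1] - A[, 1] * B[, 3],
        A[, 1] * B[, 2] - A[, 2] * B[, 1])
}

no_intersection <- function(s, label = "margin") {
  stop(structure(class = c("rodtwist_no_intersection", "error", "condition"),
                 list(message = sprintf(
                   "no intersection of the %s curve with the cross-section plane at s = %g um",
                   label, s), call = NULL, s = s)))
}

# Intersection of a margin curve with the plane through m0 with normal
# e_long. Scans precomputed dense samples for sign changes of the plane
# function and refines the bracket nearest u_hint with uniroot.
plane_intersect <- function(margin, m0, e_long, dense_u, dense_f, u_hint, s,
                            label = "margin") {
  sgn <- dense_f[-1] * dense_f[-length(dense_f)]
  idx <- which(sgn <= 0 & !(dense_f[-1] == 0 & dense_f[-length(dense_f)] == 0))
  if (!length(idx)) no_intersection(s, label)
  mids <- (dense_u[idx] + dense_u[idx + 1]) / 2
  k <- idx[which.min(abs(mids - u_hint))]
  f <- function(uu) sum((drop(margin$evaluate(uu)) - m0) * e_long)
  span <- diff(margin$domain)
  root <- stats::uniroot(f, c(dense_u[k], dense_u[k + 1]),
                         f.lower = dense_f[k], f.upper = dense_f[k + 1],
                         tol = 1e-10 * max(1, span))$root
  root
}

#' Intersection of a margin curve with the cross-section at arc length s
#'
#' The cross-section of the organ at position s is the plane through the
#' midline point m(s) perpendicular to the midline tangent. This function
#' returns the point where a margin curve pierces that plane. When the
#' plane function has several roots along the margin (strongly curved
#' organs), the root whose margin parameter is nearest `u_hint` is chosen;
#' the analysis pipeline scans s upward and seeds each search with the
#' previous accepted root.
#'
#' @param margin,midline [fit_curve()] results.
#' @param s arc-length position along the midline, micrometres, within
#'   `[0, arc_length(midline)]`.
#' @param u_hint margin parameter used to disambiguate multiple roots
#'   (default: the margin domain start).
#' @return length-3 numeric, the 3D position of the cross point (um).
#' @export
cross_section_point <- function(margin, midline, s, u_hint = margin$domain[1]) {
  stopifnot(inherits(margin, "smooth_curve"), inherits(midline, "smooth_curve"))
  total <- arc_length(midline)
  if (s < -1e-9 || s > total + 1e-9) {
    stop(sprintf("s = %g um is outside the midline arc length [0, %g]", s, total),
         call. = FALSE)
  }
  u_mid <- param_at_arclength(midline, s)
  m0 <- drop(midline$evaluate(u_mid))
  tang <- drop(midline$derivative(u_mid))
  e_long <- unit3(tang)
  dense_u <- seq(margin$domain[1], margin$domain[2], length.out = 2001)
  dense_f <- drop((margin$evaluate(dense_u) -
                     matrix(m0, length(dense_u), 3, byrow = TRUE)) %*% e_long)
  u <- plane_intersect(margin, m0, e_long, dense_u, dense_f, u_hint, s)
  drop(margin$evaluate(u))
}

# Solve arc_length(domain_start, u) = s by bracketed root-finding.
param_at_arclength <- function(curve, s) {
  if (s <= 0) return(curve$domain[1])
  f <- function(uu) arc_length(curve, curve$domain[1], uu) - s
  stats::uniroot(f, curve$domain, tol = 1e-9 * max(1, diff(curve$domain)))$root
}

#' Material frame of the organ cross-section at arc length s
#'
#' Builds the orthonormal-by-construction triple attached to the
#' cross-section at position s: `e_lateral` is the unit vector along the
#' left-minus-right margin difference (the medio-lateral direction),
#' `e_longitudinal` is the unit midline tangent, and `e_adaxial` is the
#' unit cross product `e_longitudinal x e_lateral` (the adaxial--abaxial
#' direction). `e_adaxial` is always perpendicular to the other two;
#' `e_lateral` itself is used exactly as the margins define it unless
#' `orthogonalize_lateral` projects it orthogonal to the tangent first
#' (useful when tracked margins are visibly non-perpendicular to the
#' midline).
#'
#' @param midline,left,right [fit_curve()] results for the three tracks.
#' @param s arc-length position, micrometres.
#' @param orthogonalize_lateral project the margin difference orthogonal
#'   to the tangent before normalizing (default `FALSE`, the plain
#'   definition).
#' @return An object of class `material_frame`: list with `s`,
#'   `e_lateral`, `e_longitudinal`, `e_adaxial` (unit 3-vectors).
#' @export
material_frame <- function(midline, left, right, s,
                           orthogonalize_lateral = FALSE) {
  pl <- cross_section_point(left, midline, s)
  pr <- cross_section_point(right, midline, s)
  u_mid <- param_at_arclength(midline, s)
  tang <- drop(midline$derivative(u_mid))
  frame_from_points(pl, pr, tang, s, orthogonalize_lateral)
}

frame_from_points <- function(pl, pr, tang, s, orthogonalize_lateral) {
  pl <- unname(pl); pr <- unname(pr); tang <- unname(tang)
  tn <- sqrt(sum(tang^2))
  if (tn < 1e-12) stop("degenerate midline tangent (norm < 1e-12)", call. = FALSE)
  e_long <- tang / tn
  d <- pl - pr
  if (sqrt(sum(d^2)) < 1e-6) {
    stop(sprintf("degenerate cross-section at s = %g um: margins coincide", s),
         call. = FALSE)
  }
  if (orthogonalize_lateral) {
    d <- d - sum(d * e_long) * e_long
    if (sqrt(sum(d^2)) < 1e-6) {
      stop(sprintf("degenerate cross-section at s = %g um: margin difference parallel to tangent", s),
           call. = FALSE)
    }
  }
  e_lat <- unit3(d)
  e_ad <- unit3(cross3(e_long, e_lat))
  structure(list(s = s, e_lateral = e_lat, e_longitudinal = e_long,
                 e_adaxial = e_ad), class = "material_frame")
}

#' @export
print.material_frame <- function(x, ...) {
  cat(sprintf("Material frame at s = %g um\n", x$s))
  cat(sprintf("  e_lateral      %8.5f %8.5f %8.5f\n", x$e_lateral[1],
              x$e_lateral[2], x$e_lateral[3]))
  cat(sprintf("  e_longitudinal %8.5f %8.5f %8.5f\n", x$e_longitudinal[1],
              x$e_longitudinal[2], x$e_longitudinal[3]))
  cat(sprintf("  e_adaxial      %8.5f %8.5f %8.5f\n", x$e_adaxial[1],
              x$e_adaxial[2], x$e_adaxial[3]))
  invisible(x)
}

#' Quantify twisting and bending along a tracked organ
#'
#' The central analysis of the package. Each track is Gaussian-denoised
#' ([gaussian_smooth()]) and fitted with a smooth curve ([fit_curve()]);
#' the midline is resampled at uniform arc-length steps
#' ([resample_uniform()]); at every grid position the material frame is
#' built on the perpendicular cross-section ([material_frame()]); and the
#' local deformation rates are extracted from arc-length derivatives of
#' the frame vectors (central differences on the uniform grid, one-sided
#' at the two ends):
#' \describe{
#'   \item{twist `tau(s)`}{`d e_adaxial/ds . e_lateral` — rotation of the
#'     cross-section about the midline, rad/um.}
#'   \item{lateral bending `kappa1(s)`}{`d e_longitudinal/ds . e_lateral`
#'     — midline curvature perpendicular to the adaxial direction.}
#'   \item{vertical bending `kappa2(s)`}{`d e_adaxial/ds . e_longitudinal`
#'     — midline curvature in the adaxial plane.}
#' }
#' Cumulative angles are trapezoidal integrals of the local rates from
#' s = 0, the blade--petiole junction end.
#'
#' With the ordered basis (longitudinal, lateral, adaxial), positive tau
#' means the adaxial vector rotates toward `e_lateral` with increasing s;
#' swapping the left/right margin labels flips the sign of tau, so
#' summaries also report magnitude-based statistics.
#'
#' @param tracks a [track_set].
#' @param window_um Gaussian denoising window, micrometres (default 1000;
#'   see [gaussian_smooth()]).
#' @param ds_um arc-length resampling step, micrometres (default 10).
#' @param fit_method curve-fitting method (default `"cubic"`; see
#'   [fit_curve()]).
#' @param parameterization curve parameterization (default
#'   `"chord_length"`).
#' @param orthogonalize_lateral see [material_frame()].
#' @param interior_margin_um length excluded from each end in
#'   [summary.rod_deformation()] (default 0); endpoint rates use one-sided
#'   differences and tracked organs are typically unreliable within
#'   ~200 um of the ends.
#' @return An object of class `rod_deformation`: list with `profile` (data
#'   frame: `s_um`; `tau`, `kappa1`, `kappa2` in rad/um; `twist_cum`,
#'   `bend_lat_cum`, `bend_vert_cum` in rad), `frames` (the frame vectors
#'   and cross points on the grid), `curves` (the fitted `smooth_curve`s),
#'   `config`, `source_id`.
#' @examples
#' rod <- simulate_rod(rod_spec(twist = 15 * pi / 180 / 1000))
#' fit <- rod_deformation(rod$tracks)
#' summary(fit, interior_margin_um = 200)
#' @export
rod_deformation <- function(tracks,
                            window_um = 1000, ds_um = 10,
                            fit_method = c("cubic", "poly9", "gauss8"),
                            parameterization = c("chord_length", "axis_z"),
                            orthogonalize_lateral = FALSE,
                            interior_margin_um = 0) {
  stopifnot(inherits(tracks, "track_set"))
  fit_method <- match.arg(fit_method)
  parameterization <- match.arg(parameterization)
  if (!is.finite(window_um) || window_um <= 0) stop("window_um must be positive", call. = FALSE)
  if (!is.finite(ds_um) || ds_um <= 0) stop("ds_um must be positive", call. = FALSE)
  if (!is.finite(interior_margin_um) || interior_margin_um < 0) {
    stop("interior_margin_um must be non-negative", call. = FALSE)
  }
  mid_chord <- sum(sqrt(rowSums(diff(tracks$tracks$midline)^2)))
  if (mid_chord < ds_um) {
    stop("midline chord length is shorter than the resampling step", call. = FALSE)
  }

  curves <- lapply(tracks$tracks, function(m) {
    fit_curve(gaussian_smooth(m, window_um), method = fit_method,
              parameterization = parameterization)
  })
  midline <- curves$midline
  grid <- resample_uniform(midline, ds_um)
  if (max(grid$s) < 3 * ds_um) {
    stop("midline arc length must be at least 3 resampling steps", call. = FALSE)
  }
  n <- nrow(grid)
  m_pts <- midline$evaluate(grid$u)
  tang <- midline$derivative(grid$u)

  dense_n <- max(2001L, 8L * length(midline$knots))
  margin_pts <- list()
  for (side in c("left_margin", "right_margin")) {
    mc <- curves[[side]]
    dense_u <- seq(mc$domain[1], mc$domain[2], length.out = dense_n)
    dense_pts <- mc$evaluate(dense_u)
    pts <- matrix(NA_real_, n, 3)
    hint <- mc$domain[1]
    for (i in seq_len(n)) {
      e_long <- unit3(tang[i, ])
      dense_f <- drop(dense_pts %*% e_long) - sum(m_pts[i, ] * e_long)
      u <- tryCatch(
        plane_intersect(mc, m_pts[i, ], e_long, dense_u, dense_f, hint,
                        grid$s[i], label = sub("_margin", " margin", side)),
        rodtwist_no_intersection = function(e) NA_real_)
      if (!is.na(u)) {
        pts[i, ] <- mc$evaluate(u)
        hint <- u
      }
    }
    margin_pts[[side]] <- pts
  }

  # A margin track may start or end short of the first/last section planes
  # (tracking truncation, noise); the profile covers the s range where both
  # margins cross their planes, with s rebased to the first usable section.
  # A miss strictly inside that range is a real failure and propagates.
  valid <- !is.na(margin_pts$left_margin[, 1]) & !is.na(margin_pts$right_margin[, 1])
  if (sum(valid) < 4) {
    no_intersection(grid$s[which(!valid)[1]])
  }
  first <- which(valid)[1]; last <- which(valid)[sum(valid)]
  if (!all(valid[first:last])) {
    no_intersection(grid$s[first - 1 + which(!valid[first:last])[1]])
  }
  if (first > 1 || last < n) {
    sel <- first:last
    grid <- data.frame(s = grid$s[sel] - grid$s[first], u = grid$u[sel])
    m_pts <- m_pts[sel, , drop = FALSE]
    tang <- tang[sel, , drop = FALSE]
    margin_pts <- lapply(margin_pts, function(m) m[sel, , drop = FALSE])
    n <- length(sel)
  }

  e_long <- tang / sqrt(rowSums(tang^2))
  dvec <- margin_pts$left_margin - margin_pts$right_margin
  dn <- sqrt(rowSums(dvec^2))
  if (any(dn < 1e-6)) {
    stop(sprintf("degenerate cross-section at s = %g um: margins coincide",
                 grid$s[which(dn < 1e-6)[1]]), call. = FALSE)
  }
  if (orthogonalize_lateral) {
    dvec <- dvec - rowSums(dvec * e_long) * e_long
    dn <- sqrt(rowSums(dvec^2))
    if (any(dn < 1e-6)) {
      stop("degenerate cross-section: margin difference parallel to tangent",
           call. = FALSE)
    }
  }
  e_lat <- dvec / dn
  e_ad <- cross3_rows(e_long, e_lat)
  e_ad <- e_ad / sqrt(rowSums(e_ad^2))

  d_ad <- grid_derivative(e_ad, ds_um)
  d_long <- grid_derivative(e_long, ds_um)
  tau <- rowSums(d_ad * e_lat)
  kappa1 <- rowSums(d_long * e_lat)
  kappa2 <- rowSums(d_ad * e_long)

  profile <- data.frame(s_um = grid$s, tau = tau, kappa1 = kappa1,
                        kappa2 = kappa2)
  profile$twist_cum <- cumtrapz(grid$s, tau)
  profile$bend_lat_cum <- cumtrapz(grid$s, kappa1)
  profile$bend_vert_cum <- cumtrapz(grid$s, kappa2)

  structure(list(
    profile = profile,
    frames = list(position = m_pts, e_lateral = e_lat,
                  e_longitudinal = e_long, e_adaxial = e_ad,
                  left_margin = margin_pts$left_margin,
                  right_margin = margin_pts$right_margin),
    curves = curves,
    config = list(window_um = window_um, ds_um = ds_um,
                  fit_method = fit_method, parameterization = parameterization,
                  orthogonalize_lateral = orthogonalize_lateral,
                  interior_margin_um = interior_margin_um),
    source_id = tracks$source_id
  ), class = "rod_deformation")
}

# Central differences on a uniform grid, one-sided at the two ends.
grid_derivative <- function(M, h) {
  n <- nrow(M)
  D <- matrix(NA_real_, n, ncol(M))
  D[1, ] <- (M[2, ] - M[1, ]) / h
  D[n, ] <- (M[n, ] - M[n - 1, ]) / h
  if (n > 2) {
    D[2:(n - 1), ] <- (M[3:n, , drop = FALSE] - M[1:(n - 2), , drop = FALSE]) / (2 * h)
  }
  D
}

cumtrapz <- function(x, y) {
  n <- length(x)
  c(0, cumsum((y[-1] + y[-n]) / 2 * diff(x)))
}

#' Recompute cumulative angles from the local rate columns
#'
#' Cumulative twist and bending angles are the trapezoidal integrals of
#' the local rates from s = 0 (the blade--petiole junction end); the value
#' at s = 0 is 0 by construction.
#'
#' @param profile a `rod_deformation` object or a profile data frame.
#' @return the input with its cumulative columns recomputed.
#' @export
cumulative_angles <- function(profile) {
  p <- profile_df(profile)
  if (any(!is.finite(as.matrix(p[, c("s_um", "tau", "kappa1", "kappa2")])))) {
    stop("local rate columns contain non-finite values", call. = FALSE)
  }
  p$twist_cum <- cumtrapz(p$s_um, p$tau)
  p$bend_lat_cum <- cumtrapz(p$s_um, p$kappa1)
  p$bend_vert_cum <- cumtrapz(p$s_um, p$kappa2)
  if (inherits(profile, "rod_deformation")) {
    profile$profile <- p
    profile
  } else {
    p
  }
}

#' Summary statistics of a deformation profile
#'
#' Mean and population standard deviation of the local twist rate
#' (reported in degrees/mm, the field's customary unit) and the maxima of
#' the absolute cumulative twist and bending angles (degrees), computed
#' over the grid after excluding `interior_margin_um` from each end.
#' Organ ends are typically unreliable (one-sided differences, tracking
#' truncation), so a 200 um margin is a reasonable choice for real data.
#'
#' @param profile a `rod_deformation` object or a profile data frame.
#' @param interior_margin_um length excluded from each end, micrometres.
#' @return list of class `rod_profile_summary` with fields
#'   `mean_twist_deg_per_mm`, `sd_twist_deg_per_mm`,
#'   `max_abs_cum_twist_deg`, `max_abs_cum_bend_deg`,
#'   `measured_length_um`.
#' @export
summarize_profile <- function(profile, interior_margin_um = 0) {
  p <- profile_df(profile)
  if (!is.finite(interior_margin_um) || interior_margin_um < 0) {
    stop("interior_margin_um must be non-negative", call. = FALSE)
  }
  total <- max(p$s_um)
  keep <- p$s_um >= interior_margin_um & p$s_um <= total - interior_margin_um
  if (sum(keep) < 2) {
    stop("interior margin leaves fewer than 2 grid points", call. = FALSE)
  }
  k <- p[keep, ]
  deg_per_mm <- 180 / pi * 1000
  deg <- 180 / pi
  tau <- k$tau * deg_per_mm
  out <- list(
    mean_twist_deg_per_mm = mean(tau),
    sd_twist_deg_per_mm = sqrt(mean((tau - mean(tau))^2)),
    max_abs_cum_twist_deg = max(abs(k$twist_cum)) * deg,
    max_abs_cum_bend_deg = max(abs(c(k$bend_lat_cum, k$bend_vert_cum))) * deg,
    measured_length_um = total
  )
  structure(out, class = "rod_profile_summary",
            interior_margin_um = interior_margin_um)
}

#' @export
print.rod_profile_summary <- function(x, ...) {
  cat("Deformation summary\n")
  cat(sprintf("  measured length      %10.1f um (interior margin %g um)\n",
              x$measured_length_um, attr(x, "interior_margin_um")))
  cat(sprintf("  local twist          %10.2f deg/mm (s.d. %.2f, |mean| %.2f)\n",
              x$mean_twist_deg_per_mm, x$sd_twist_deg_per_mm,
              abs(x$mean_twist_deg_per_mm)))
  cat(sprintf("  max |cum. twist|     %10.2f deg\n", x$max_abs_cum_twist_deg))
  cat(sprintf("  max |cum. bending|   %10.2f deg\n", x$max_abs_cum_bend_deg))
  invisible(x)
}

#' @rdname summarize_profile
#' @param object a `rod_deformation` object.
#' @param ... unused.
#' @export
summary.rod_deformation <- function(object,
                                    interior_margin_um = object$config$interior_margin_um,
                                    ...) {
  summarize_profile(object, interior_margin_um)
}

#' @export
print.rod_deformation <- function(x, ...) {
  p <- x$profile
  cat("Rod deformation profile",
      if (nzchar(x$source_id)) paste0("(", x$source_id, ")"), "\n")
  cat(sprintf("  %d grid points, s = 0 .. %.1f um (ds = %g um)\n",
              nrow(p), max(p$s_um), x$config$ds_um))
  cat(sprintf("  smoothing window %g um, %s fit, %s parameterization\n",
              x$config$window_um, x$config$fit_method,
              x$config$parameterization))
  dpm <- 180 / pi * 1000
  cat(sprintf("  twist rate: mean %.2f deg/mm; cumulative twist at tip %.1f deg\n",
              mean(p$tau) * dpm, p$twist_cum[nrow(p)] * 180 / pi))
  invisible(x)
}

#' @export
as.data.frame.rod_deformation <- function(x, ...) x$profile

#' @export
coef.rod_deformation <- function(object, ...) {
  p <- object$profile
  dpm <- 180 / pi * 1000
  c(mean_twist_deg_per_mm = mean(p$tau) * dpm,
    mean_kappa1_deg_per_mm = mean(p$kappa1) * dpm,
    mean_kappa2_deg_per_mm = mean(p$kappa2) * dpm)
}

#' Plot local rates and cumulative angles along the organ
#'
#' @param x a `rod_deformation` object.
#' @param ... passed to `matplot`.
#' @export
plot.rod_deformation <- function(x, ...) {
  p <- x$profile
  dpm <- 180 / pi * 1000
  deg <- 180 / pi
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1.5, 1))
  on.exit(graphics::par(op))
  graphics::matplot(p$s_um, cbind(p$tau, p$kappa1, p$kappa2) * dpm,
                    type = "l", lty = 1, col = c("blue", "red", "orange"),
                    xlab = "s (um)", ylab = "local rate (deg/mm)", ...)
  graphics::legend("topright", c("twist", "lateral bend", "vertical bend"),
                   lty = 1, col = c("blue", "red", "orange"), bty = "n")
  graphics::matplot(p$s_um,
                    cbind(p$twist_cum, p$bend_lat_cum, p$bend_vert_cum) * deg,
                    type = "l", lty = 1, col = c("blue", "red", "orange"),
                    xlab = "s (um)", ylab = "cumulative angle (deg)", ...)
  invisible(x)
}
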