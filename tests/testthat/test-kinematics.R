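test_that("cross-section intersection is exact on axis-aligned and rotated rods", {
  z <- seq(0, 3200, by = 100)
  midline <- fit_curve(cbind(0, 0, z))
  margin <- fit_curve(cbind(100, 0, z))
  p <- cross_section_point(margin, midline, 1000)
  expect_equal(p, c(100, 0, 1000), tolerance = 1e-6, ignore_attr = TRUE)

  # tilt the whole configuration 30 degrees in the x-z plane: the
  # intersection must be the rotated point
  R <- rotation_about(c(0, 1, 0), pi / 6)
  mid_r <- fit_curve(cbind(0, 0, z) %*% t(R))
  mar_r <- fit_curve(cbind(100, 0, z) %*% t(R))
  p_r <- cross_section_point(mar_r, mid_r, 1000)
  expect_equal(p_r, drop(c(100, 0, 1000) %*% t(R)), tolerance = 1e-6,
               ignore_attr = TRUE)

  # brute-force oracle: minimize the plane function over dense samples
  uu <- seq(mar_r$domain[1], mar_r$domain[2], length.out = 1e5)
  e_long <- drop(R %*% c(0, 0, 1))
  m_s <- drop(c(0, 0, 1000) %*% t(R))
  f <- abs(drop((mar_r$evaluate(uu) -
                   matrix(m_s, length(uu), 3, byrow = TRUE)) %*% e_long))
  brute <- drop(mar_r$evaluate(uu[which.min(f)]))
  expect_equal(p_r, brute, tolerance = 0.05, ignore_attr = TRUE)

  # margin truncated before the plane -> no-intersection error carrying s
  short_margin <- fit_curve(cbind(100, 0, seq(0, 1500, by = 100)))
  err <- tryCatch(cross_section_point(short_margin, midline, 2500),
                  rodtwist_no_intersection = function(e) e)
  expect_s3_class(err, "rodtwist_no_intersection")
  expect_equal(err$s, 2500)
  expect_error(cross_section_point(margin, midline, 5000), "outside")
})

test_that("the material frame is the axis-aligned triple on a straight rod", {
  z <- seq(0, 3200, by = 100)
  midline <- fit_curve(cbind(0, 0, z))
  left <- fit_curve(cbind(100, 0, z))
  right <- fit_curve(cbind(-100, 0, z))
  fr <- material_frame(midline, left, right, 1600)
  expect_equal(fr$e_lateral, c(1, 0, 0), tolerance = 1e-9)
  expect_equal(fr$e_longitudinal, c(0, 0, 1), tolerance = 1e-9)
  expect_equal(fr$e_adaxial, c(0, 1, 0), tolerance = 1e-9)
})

test_that("frames stay orthonormal-by-construction for oblique margins", {
  # margins offset 10 degrees from perpendicular to the tangent
  z <- seq(0, 3200, by = 100)
  shift <- tan(10 * pi / 180) * 100
  midline <- fit_curve(cbind(0, 0, z))
  left <- fit_curve(cbind(100, 0, z + shift))
  right <- fit_curve(cbind(-100, 0, z - shift))
  fr <- material_frame(midline, left, right, 1600)
  # both cross points lie in the section plane, so the margin difference
  # is perpendicular to the tangent even for obliquely tracked margins
  expect_lt(abs(sum(fr$e_lateral * fr$e_longitudinal)), 1e-9)
  # e_adaxial is the explicit unit cross product, orthogonal to both
  pl <- unname(cross_section_point(left, midline, 1600))
  pr <- unname(cross_section_point(right, midline, 1600))
  oracle <- cross3(c(0, 0, 1), (pl - pr) / sqrt(sum((pl - pr)^2)))
  expect_equal(fr$e_adaxial, oracle / sqrt(sum(oracle^2)), tolerance = 1e-9)
  expect_equal(sqrt(sum(fr$e_adaxial^2)), 1, tolerance = 1e-9)
  expect_lt(abs(sum(fr$e_adaxial * fr$e_longitudinal)), 1e-9)
  expect_lt(abs(sum(fr$e_adaxial * fr$e_lateral)), 1e-9)

  # opt-in orthogonalization makes e_lateral perpendicular to the tangent
  fr2 <- material_frame(midline, left, right, 1600,
                        orthogonalize_lateral = TRUE)
  expect_lt(abs(sum(fr2$e_lateral * fr2$e_longitudinal)), 1e-9)

  # coincident margins -> degenerate section
  expect_error(material_frame(midline, left, left, 1600), "degenerate")
})

test_that("a straight untwisted rod yields identically zero rates", {
  fit <- rod_deformation(straight_rod_tracks(), window_um = 1000, ds_um = 10)
  p <- fit$profile
  expect_lt(max(abs(p$tau)), 1e-6)
  expect_lt(max(abs(p$kappa1)), 1e-6)
  expect_lt(max(abs(p$kappa2)), 1e-6)
  expect_equal(p$twist_cum[1], 0)
})

test_that("cumulative angles are the trapezoidal integral of the local rates", {
  rod <- simulate_rod(rod_spec(twist = 15 * DEG_PER_MM, kappa2 = 1 / 50000))
  fit <- rod_deformation(rod$tracks)
  p <- fit$profile
  ds <- diff(p$s_um)
  trap <- function(y) c(0, cumsum((y[-1] + y[-length(y)]) / 2 * ds))
  expect_equal(p$twist_cum, trap(p$tau), tolerance = 1e-9)
  expect_equal(p$bend_lat_cum, trap(p$kappa1), tolerance = 1e-9)
  expect_equal(p$bend_vert_cum, trap(p$kappa2), tolerance = 1e-9)
  expect_equal(cumulative_angles(p), p, tolerance = 1e-12)

  # linear rate from 0 to 30 deg/mm over 3.2 mm: analytic quadratic integral
  s <- seq(0, 3200, by = 10)
  lin <- data.frame(s_um = s, tau = 30 * DEG_PER_MM * s / 3200,
                    kappa1 = 0, kappa2 = 0)
  cum <- cumulative_angles(lin)
  analytic <- 30 * DEG_PER_MM * s^2 / (2 * 3200)
  expect_equal(cum$twist_cum[-1], analytic[-1], tolerance = 1e-3)

  lin$tau[5] <- Inf
  expect_error(cumulative_angles(lin), "non-finite")
})

test_that("profile summaries report deg/mm statistics over the retained interior", {
  s <- seq(0, 3200, by = 10)
  const <- data.frame(s_um = s, tau = 15 * DEG_PER_MM, kappa1 = 0, kappa2 = 0,
                      twist_cum = 15 * DEG_PER_MM * s, bend_lat_cum = 0,
                      bend_vert_cum = 0)
  sm <- summarize_profile(const, 200)
  expect_equal(sm$mean_twist_deg_per_mm, 15)
  expect_equal(sm$sd_twist_deg_per_mm, 0)
  expect_equal(sm$max_abs_cum_twist_deg, 15 * (3200 - 200) / 1000)
  expect_equal(sm$max_abs_cum_bend_deg, 0)
  expect_equal(sm$measured_length_um, 3200)

  # three equal-length segments at 12 / 15 / 18 deg/mm average to 15
  n <- length(s)
  seg <- rep(c(12, 15, 18) * DEG_PER_MM, each = 107)[1:n]
  three <- data.frame(s_um = s, tau = seg, kappa1 = 0, kappa2 = 0,
                      twist_cum = 0, bend_lat_cum = 0, bend_vert_cum = 0)
  expect_equal(summarize_profile(three, 5)$mean_twist_deg_per_mm, 15,
               tolerance = 0.02)

  expect_error(summarize_profile(const, 1700), "fewer than 2")
})

test_that("rates are invariant under rigid motions of the input tracks", {
  rod <- simulate_rod(rod_spec(twist = 15 * DEG_PER_MM, kappa2 = 1 / 20000))
  base <- rod_deformation(rod$tracks)$profile
  moved <- transform_tracks(rod$tracks, rotation_about(c(1, 2, 3), 0.7),
                            c(500, -300, 200))
  p <- rod_deformation(moved)$profile
  expect_lt(max(abs(p$tau - base$tau)), 1e-6)
  expect_lt(max(abs(p$kappa1 - base$kappa1)), 1e-6)
  expect_lt(max(abs(p$kappa2 - base$kappa2)), 1e-6)
})

test_that("mirror reflection flips the twist chirality but not bending magnitude", {
  rod <- simulate_rod(rod_spec(twist = 15 * DEG_PER_MM, kappa2 = 1 / 20000))
  base <- rod_deformation(rod$tracks)$profile
  mir <- lapply(rod$tracks$tracks, function(m) { m[, 1] <- -m[, 1]; m })
  p <- rod_deformation(track_set(mir$midline, mir$left_margin,
                                 mir$right_margin))$profile
  expect_lt(max(abs(p$tau + base$tau)), 1e-6)
  expect_lt(max(abs(abs(p$kappa2) - abs(base$kappa2))), 1e-6)
})

test_that("swapping margin labels negates e_lateral and the bending rates but not tau", {
  # tau is a chirality: relabelling left/right negates both e_lateral and
  # e_adaxial, so their pairing in tau is unchanged, while kappa1 and
  # kappa2 (one flipped vector each) change sign
  rod <- simulate_rod(rod_spec(twist = 15 * DEG_PER_MM, kappa2 = 1 / 20000))
  fit <- rod_deformation(rod$tracks)
  sw <- rod_deformation(track_set(rod$tracks$tracks$midline,
                                  rod$tracks$tracks$right_margin,
                                  rod$tracks$tracks$left_margin))
  expect_equal(sw$frames$e_lateral, -fit$frames$e_lateral, tolerance = 1e-9)
  expect_lt(max(abs(sw$profile$tau - fit$profile$tau)), 1e-6)
  expect_lt(max(abs(sw$profile$kappa1 + fit$profile$kappa1)), 1e-6)
  expect_lt(max(abs(sw$profile$kappa2 + fit$profile$kappa2)), 1e-6)
})

test_that("halving the grid step barely changes the interior twist", {
  rod <- simulate_rod(rod_spec(twist = 15 * DEG_PER_MM))
  p10 <- rod_deformation(rod$tracks, ds_um = 10)$profile
  p5 <- rod_deformation(rod$tracks, ds_um = 5)$profile
  m10 <- mean(p10$tau[interior(p10$s_um, 200)])
  m5 <- mean(p5$tau[interior(p5$s_um, 200)])
  expect_lt(abs(m5 - m10) / abs(m10), 0.005)
})
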