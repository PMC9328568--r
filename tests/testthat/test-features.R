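test_that("polygon area, centroid and perimeter match closed forms", {
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  expect_equal(polygon_area(sq), 1)
  expect_equal(polygon_centroid(sq), c(0.5, 0.5))

  # regular 360-gon of circumradius 1: area n/2 sin(2 pi/n)
  ngon <- circle_contour(1, 360)
  expect_equal(polygon_area(ngon), 360 / 2 * sin(2 * pi / 360), tolerance = 1e-12)
  expect_equal(polygon_area(ngon), pi, tolerance = 1e-4)

  # clockwise triangle: orientation-independent
  tri <- rbind(c(0, 0), c(0, 1), c(1, 0))
  expect_equal(polygon_area(tri), 0.5)

  circ <- circle_contour(0.7, 200, center = c(2, 3))
  expect_equal(polygon_centroid(circ), c(2, 3), tolerance = 1e-9)

  # L-shaped polygon centroid vs dense-raster averaging oracle
  ell <- rbind(c(0, 0), c(2, 0), c(2, 1), c(1, 1), c(1, 3), c(0, 3))
  expect_equal(polygon_centroid(ell),
               raster_centroid_oracle(ell, pixel = 2e-3), tolerance = 1e-3)

  bow <- rbind(c(0, 0), c(1, 1), c(1, 0), c(0, 1))  # self-intersecting
  expect_error(polygon_area(bow, check_simple = TRUE), "self-intersecting")
  expect_error(polygon_area(rbind(c(0, 0), c(1, 1))), "3 vertices")
  expect_error(polygon_centroid(rbind(c(0, 0), c(1, 0), c(2, 0))), "degenerate")
})

test_that("calcification angle is the union of subtended intervals", {
  sec90 <- annulus_section(calc = list(sector_annulus_contour(1.05, 1.5, 10, 100)))
  expect_equal(calcification_angle(sec90), 90, tolerance = 0.1)

  two <- annulus_section(calc = list(
    sector_annulus_contour(1.05, 1.5, 0, 30),
    sector_annulus_contour(1.05, 1.5, 180, 220)))
  expect_equal(calcification_angle(two), 70, tolerance = 0.1)

  # overlapping deposits 0-50 and 40-90 cover 90 degrees, not 100
  ovl <- annulus_section(calc = list(
    sector_annulus_contour(1.05, 1.5, 0, 50),
    sector_annulus_contour(1.3, 1.7, 40, 90)))
  expect_equal(calcification_angle(ovl), 90, tolerance = 0.1)
  expect_equal(calcification_angle(ovl),
               raycast_angle_oracle(ovl, 0.01, theta_min = -10, theta_max = 110),
               tolerance = 0.05)

  expect_equal(calcification_angle(annulus_section()), 0)

  # deposit straddling the 0-degree seam
  seam <- annulus_section(calc = list(sector_annulus_contour(1.05, 1.5, -30, 25)))
  expect_equal(calcification_angle(seam), 55, tolerance = 0.1)
})

test_that("angle and thickness are invariant to rigid motions", {
  base <- annulus_section(calc = list(
    sector_annulus_contour(1.05, 1.45, 20, 140),
    sector_annulus_contour(1.05, 1.35, 200, 230)))
  a0 <- calcification_angle(base)
  t0 <- max_calc_thickness(base, n_rays = 720)
  set.seed(11)
  for (k in 1:5) {
    phi <- stats::runif(1, 0, 2 * pi)
    shift <- stats::runif(2, -3, 3)
    rot <- matrix(c(cos(phi), sin(phi), -sin(phi), cos(phi)), 2)
    tf <- function(m) sweep(m %*% t(rot), 2, -shift)
    moved <- cross_section(0, tf(base$lumen_contour), tf(base$outer_contour),
                           lapply(base$calc_regions, tf), validate = FALSE)
    expect_equal(calcification_angle(moved), a0, tolerance = 1e-9)
    # ray grids are re-derived in the rotated frame, so thickness is
    # invariant only up to the grid discretization
    expect_equal(max_calc_thickness(moved, n_rays = 720), t0, tolerance = 1e-5)
  }
})

test_that("maximum calcification thickness matches ray oracles", {
  sec <- annulus_section(calc = list(sector_annulus_contour(1.05, 1.55, 30, 120)))
  expect_equal(max_calc_thickness(sec), 0.5, tolerance = 1e-3)
  expect_equal(max_calc_thickness(annulus_section()), 0)

  # crescent-like deposit: thin at the tips, thick in the middle
  th <- seq(40, 140, length.out = 60) * pi / 180
  rin <- 1.05 + 0.25 * sin((th - th[1]) / (th[60] - th[1]) * pi)
  crescent <- rbind(cbind(rin * cos(th), rin * sin(th)),
                    cbind(1.6 * cos(rev(th)), 1.6 * sin(rev(th))))
  sec <- annulus_section(calc = list(crescent))
  expect_equal(max_calc_thickness(sec, n_rays = 7200),
               dense_ray_thickness_oracle(sec, n_rays = 10000),
               tolerance = 1e-3)
})

test_that("inner arc lengths partition the lumen perimeter", {
  lum <- circle_contour(1, 720)
  sec <- cross_section(0, lum, circle_contour(2, 720),
                       list(sector_annulus_contour(1.02, 1.5, 0, 90)),
                       validate = FALSE)
  arcs <- inner_arc_lengths(sec)
  expect_equal(unname(arcs["arclength_c"]), pi / 2, tolerance = 2e-3)
  expect_equal(unname(arcs["arclength_f"]), 3 * pi / 2, tolerance = 2e-3)
  # the two parts sum to the perimeter (same segments, re-grouped)
  expect_equal(sum(arcs), polygon_perimeter(lum), tolerance = 1e-14)

  none <- annulus_section()
  arcs0 <- inner_arc_lengths(none)
  expect_equal(unname(arcs0["arclength_c"]), 0)
  expect_equal(sum(arcs0), polygon_perimeter(none$lumen_contour))

  # ellipse lumen with a 120-degree deposit vs the arc-integration oracle
  th <- seq(0, 2 * pi, length.out = 721)[-721]
  ell <- cbind(1.4 * cos(th), 0.9 * sin(th))
  sec <- cross_section(0, ell, circle_contour(2.4, 720),
                       list(sector_annulus_contour(1.45, 1.8, 100, 220, n_arc = 120)),
                       validate = FALSE)
  arcs <- inner_arc_lengths(sec)
  u <- stentml:::calc_angular_union(sec)
  oracle <- arc_partition_oracle(ell, u)
  expect_equal(unname(arcs["arclength_c"]), oracle[1], tolerance = 1e-6)
  expect_equal(unname(arcs["arclength_f"]), oracle[2], tolerance = 1e-6)
})

test_that("extracted features of constructed annuli match closed forms", {
  sec <- annulus_section(r_in = 1, r_out = 2, n = 1440)
  fv <- extract_features(sec)
  expect_equal(unname(fv["area_a"]), 4 * pi, tolerance = 1e-4)
  expect_equal(unname(fv["area_l"]), pi, tolerance = 1e-4)
  expect_equal(unname(fv["area_f"]), 3 * pi, tolerance = 1e-4)
  expect_equal(unname(fv["area_c"]), 0)
  expect_equal(unname(fv["angle_c"]), 0)
  expect_equal(unname(fv["thickness_c"]), 0)
  expect_equal(unname(fv["arclength_c"]), 0)
  expect_equal(unname(fv["arclength_f"]), 2 * pi, tolerance = 1e-4)

  # 180-degree sector deposit of radial extent 0.3 seated at r = 1.05
  sec <- annulus_section(r_in = 1, r_out = 2, n = 1440,
                         calc = list(sector_annulus_contour(1.05, 1.35, 0, 180,
                                                            n_arc = 361)))
  fv <- extract_features(sec)
  expect_equal(unname(fv["angle_c"]), 180, tolerance = 0.05)
  expect_equal(unname(fv["arclength_c"]), pi, tolerance = 5e-3)
  expect_equal(unname(fv["thickness_c"]), 0.3, tolerance = 1e-3)
  expect_equal(unname(fv["area_c"]), 0.5 * pi * (1.35^2 - 1.05^2),
               tolerance = 1e-3)
  expect_equal(unname(fv["area_f"]),
               unname(fv["area_a"] - fv["area_l"] - fv["area_c"]))
})

test_that("polygon features agree with 12.5 um raster recomputation", {
  vessel <- generate_vessel(vessel_gen_config(n_sections = 50, seed = 99,
                                              axial_correlation_length = 0.5))
  feats <- extract_features_vessel(vessel)
  for (i in seq_along(vessel)) {
    m <- rasterize_section(vessel[[i]], 0.0125)
    a <- mask_areas(m)
    expect_equal(unname(a["lumen"]), feats$area_l[i], tolerance = 0.02)
    expect_equal(unname(a["fibrotic"]), feats$area_f[i], tolerance = 0.02)
    if (feats$area_c[i] > 0.05)
      expect_equal(unname(a["calcification"]), feats$area_c[i], tolerance = 0.02)
  }
})

test_that("sector-style slices keep arc length and angle conventions consistent", {
  # on circular lumens, arclength_c / perimeter should equal angle_c / 360
  # up to the angular quantization of the lumen contour (1 degree here)
  vessel <- generate_vessel(vessel_gen_config(n_sections = 12, seed = 3,
                                              lumen_ellipticity = 0,
                                              contour_points = 360))
  feats <- extract_features_vessel(vessel)
  per <- feats$arclength_c + feats$arclength_f
  has_calc <- feats$angle_c > 1
  expect_true(any(has_calc))
  expect_lt(max(abs(feats$arclength_c[has_calc] / per[has_calc] -
                    feats$angle_c[has_calc] / 360)), 0.005)
})

test_that("neighbor averaging truncates the window at segment ends", {
  n <- 20
  feats <- data.frame(slice_index = 1:n, z = (1:n) / 10)
  for (nm in stentml:::FEATURE_NAMES) feats[[nm]] <- seq(1, 5, length.out = n)
  out <- neighbor_average(feats)
  # linear ramp: interior slices unchanged (symmetric window)
  expect_equal(out$area_a[5:16], feats$area_a[5:16], tolerance = 1e-12)
  # slice 1: mean over slices 1-5
  expect_equal(out$area_a[1], mean(feats$area_a[1:5]))
  expect_equal(out$area_a[2], mean(feats$area_a[1:6]))
  expect_equal(nrow(out), n)

  const <- feats
  for (nm in stentml:::FEATURE_NAMES) const[[nm]] <- 7
  expect_equal(neighbor_average(const), const)
})
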