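# Tooth/sinus detection and geometry, and the aggregated margin summary.

sin_lobe_contour <- function(k = 12, r0 = 100, amp = 8, n = 4096) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  leaf_contour(cbind((r0 + amp * sin(k * th)) * cos(th),
                     (r0 + amp * sin(k * th)) * sin(th)))
}

test_that("a k-lobed circle yields k interleaved tips and valleys", {
  # oracle: analytic extrema of r(phi) = 100 + 8 sin(12 phi)
  ct <- sin_lobe_contour(12)
  ex <- detect_extrema(radial_profile(ct))
  expect_length(ex$tips, 12)
  expect_length(ex$valleys, 12)
  # interleaving: exactly one valley between consecutive tips
  both <- rbind(cbind(ex$tips, 1), cbind(ex$valleys, -1))
  both <- both[order(both[, 1]), ]
  expect_true(all(diff(both[, 2]) != 0))
})

test_that("a near-circular smooth ellipse yields no teeth", {
  # oracle: the radial-profile maxima of an ellipse have prominence a - b,
  # below the default threshold for this eccentricity
  ct <- ellipse_contour(100, 98.5)
  pr <- radial_profile(ct)
  expect_lt(100 - 98.5, 1.5 + 0.02 * median(pr$distances))
  ex <- detect_extrema(pr)
  expect_length(ex$tips, 0)
})

test_that("tooth geometry matches the shoelace/triangle oracles", {
  # triangular tooth, base 20, height 10, on a long flat baseline
  xs <- seq(0, 200, by = 0.25)
  ys <- rep(0, length(xs))
  in_tooth <- xs >= 90 & xs <= 110
  ys[in_tooth] <- 10 * (1 - abs(xs[in_tooth] - 100) / 10)
  top <- cbind(xs, 40 + ys)
  poly <- leaf_contour(rbind(top, cbind(rev(xs), 0)))
  ex <- detect_extrema(radial_profile(poly))
  tg <- suppressWarnings(tooth_geometry(poly, ex$tips, ex$valleys))
  expect_length(tg, 1)
  expect_lt(abs(tg[[1]]$height - 10), 0.5)
  expect_lt(abs(tg[[1]]$area - 100), 5)   # shoelace oracle: 0.5 * 20 * 10
  s <- tg[[1]]$tip_angle + tg[[1]]$left_angle + tg[[1]]$right_angle
  expect_lt(abs(s - 180), 0.1)

  # equilateral: base 20, height 10*sqrt(3)
  ys2 <- rep(0, length(xs))
  ys2[in_tooth] <- 10 * sqrt(3) * (1 - abs(xs[in_tooth] - 100) / 10)
  poly2 <- leaf_contour(rbind(cbind(xs, 40 + ys2), cbind(rev(xs), 0)))
  ex2 <- detect_extrema(radial_profile(poly2))
  tg2 <- suppressWarnings(tooth_geometry(poly2, ex2$tips, ex2$valleys))
  expect_lt(abs(tg2[[1]]$tip_angle - 60), 2)
})

test_that("valley geometry mirrors tooth geometry on the symmetric lobed fixture", {
  # high lobe count keeps the chord sagitta of the circular baseline small
  # relative to the lobe amplitude, so tooth and valley measures mirror
  ct <- sin_lobe_contour(30, amp = 10)
  ex <- detect_extrema(radial_profile(ct))
  tg <- tooth_geometry(ct, ex$tips, ex$valleys)
  vg <- valley_geometry(ct, ex$tips, ex$valleys)
  expect_length(vg, 30)
  md <- mean(vapply(vg, `[[`, numeric(1), "depth"))
  mh <- mean(vapply(tg, `[[`, numeric(1), "height"))
  expect_lt(abs(md - mh) / mh, 0.10)     # sinusoid symmetry
  expect_gt(sum(vapply(vg, `[[`, numeric(1), "area")), 0)

  # toothless margin: no valley records
  ex0 <- detect_extrema(radial_profile(ellipse_contour(100, 99)))
  expect_length(valley_geometry(ellipse_contour(100, 99), ex0$tips, ex0$valleys), 0)
})

test_that("serration_summary aggregates and partitions the blade consistently", {
  gen <- make_leaflet_contour(leaflet_spec(tooth_count = 8, margin_noise_sd = 0, seed = 3))
  row <- measure_leaflet_contour(gen$contour)
  expect_equal(row$tooth_number, 8)
  # 8 nearly identical teeth: total close to 8 x the mean
  expect_lt(abs(row$total_tooth_area - 8 * row$mean_tooth_area) / row$total_tooth_area, 1e-9)
  expect_lt(abs(row$total_tooth_area / 8 - row$mean_tooth_area) / row$mean_tooth_area, 0.02)
  # identity: inner blade area = blade area - outer + inner toothed area
  expect_equal(row$inner_blade_area,
               row$blade_area - row$outer_toothed_area + row$inner_toothed_area,
               tolerance = 1e-9)
  expect_equal(row$relative_tooth_area, row$total_tooth_area / row$blade_area,
               tolerance = 1e-9)
  expect_true(row$inner_toothed_area_ratio >= 0 && row$inner_toothed_area_ratio <= 1)
  expect_equal(row$tooth_number_blade_ratio, 8 / row$blade_area, tolerance = 1e-9)
})

test_that("a smooth-margin leaflet reports zero teeth and zero tooth density", {
  gen <- make_leaflet_contour(leaflet_spec(tooth_count = 0, seed = 2))
  row <- suppressWarnings(measure_leaflet_contour(gen$contour))
  expect_equal(row$tooth_number, 0)
  expect_equal(row$tooth_number_blade_ratio, 0)
  expect_equal(row$total_tooth_area, 0)
  expect_true(is.na(row$tooth_valley_area_ratio))
})

test_that("the tooth/valley area ratio of the symmetric lobed fixture is near 1", {
  ct <- sin_lobe_contour(40, amp = 10)
  ex <- detect_extrema(radial_profile(ct))
  tg <- tooth_geometry(ct, ex$tips, ex$valleys)
  vg <- valley_geometry(ct, ex$tips, ex$valleys)
  ratio <- sum(vapply(tg, `[[`, numeric(1), "area")) /
    sum(vapply(vg, `[[`, numeric(1), "area"))
  expect_lt(abs(ratio - 1), 0.1)
})

test_that("doubling the scale doubles heights and quadruples areas", {
  # teeth sized so the margin detail stays inside the detector's baseline
  # window at both scales
  gen <- make_leaflet_contour(leaflet_spec(tooth_count = 20, tooth_base_width = 16,
                                           seed = 5))
  r1 <- measure_leaflet_contour(gen$contour)
  big <- leaf_contour(contour_points(gen$contour) * 2)
  r2 <- measure_leaflet_contour(big)
  expect_equal(r2$tooth_number, r1$tooth_number)
  expect_lt(abs(r2$blade_length / r1$blade_length - 2), 0.04)
  expect_lt(abs(r2$total_tooth_area / r1$total_tooth_area - 4), 0.08)
  # heights depend on where the sinus minimum lands on its nearly flat
  # floor, which jitters with sampling phase
  expect_lt(abs(r2$mean_tooth_height / r1$mean_tooth_height - 2), 0.12)
})

test_that("tooth counts are recovered exactly across the node-series spectrum", {
  for (k in c(6, 14, 23, 33, 40)) {
    gen <- make_leaflet_contour(recovery_spec(k, seed = 17 + k))
    expect_equal(suppressWarnings(measure_leaflet_contour(gen$contour))$tooth_number, k)
  }
})
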