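# Elliptic Fourier description: invariances, band powers, reconstruction
# and the spectral low-pass filter.

test_that("a circle concentrates all spectral power in the first harmonic", {
  sp <- efd_transform(ellipse_contour(100), n_harmonics = 40)
  expect_lt(sum(sp$amplitude[-1]^2) / sp$amplitude[1]^2, 1e-3)
  expect_lt(abs(sp$amplitude[1] - 100 * sqrt(2)), 0.5)
})

test_that("amplitudes are invariant to translation, rotation and starting point", {
  gen <- make_leaflet_contour(leaflet_spec(tooth_count = 12, seed = 2))
  pts <- contour_points(gen$contour)
  a0 <- efd_transform(gen$contour)$amplitude

  a_tr <- efd_transform(leaf_contour(sweep(pts, 2, c(-31, 12))))$amplitude
  expect_lt(max(abs(a_tr - a0)) / max(a0), 1e-6)

  R <- leafletkit:::rot2(37 * pi / 180)
  pts2 <- (pts %*% t(R))[c(102:nrow(pts), 1:101), ]
  a_rs <- efd_transform(leaf_contour(pts2))$amplitude
  expect_lt(max(abs(a_rs - a0)) / max(a0), 1e-4)
})

test_that("size is preserved: scaling the contour scales every amplitude", {
  gen <- make_leaflet_contour(leaflet_spec(tooth_count = 12, seed = 3))
  a0 <- efd_transform(gen$contour)$amplitude
  a2 <- efd_transform(leaf_contour(contour_points(gen$contour) * 2))$amplitude
  keep <- a0 > 1e-6
  expect_lt(max(abs(a2[keep] / a0[keep] - 2)), 1e-6)
})

test_that("Delta + Alpha + Beta partition total power exactly and half-power cases hold", {
  gen <- make_leaflet_contour(leaflet_spec(tooth_count = 15, seed = 4))
  sp <- efd_transform(gen$contour)
  bs <- band_summary(sp)
  expect_identical(bs$delta_power + bs$alpha_power + bs$beta_power,
                   sum(sp$amplitude^2))

  # single-harmonic spectrum (all power at f = 1): a circle under arc-length
  # parameterization, and a synthetic first-harmonic-only spectrum
  spe <- efd_transform(ellipse_contour(90))
  expect_equal(band_summary(spe)$half_power_frequency, 1)
  sp1 <- sp; sp1$amplitude <- c(5, rep(0, 119))
  expect_equal(band_summary(sp1)$half_power_frequency, 1)

  # synthetic spectrum with equal power at f = 10 and f = 30 (oracle:
  # direct cumulative sum under the cumulative->=-half rule)
  spx <- sp
  spx$amplitude <- rep(0, 120); spx$amplitude[c(10, 30)] <- 3
  expect_equal(band_summary(spx, mode = "power")$half_power_frequency, 10)

  spz <- sp; spz$amplitude <- rep(0, 120)
  expect_error(band_summary(spz), "zero total")
})

test_that("full-spectrum reconstruction returns to the original outline", {
  gen <- make_leaflet_contour(leaflet_spec(tooth_count = 12, seed = 5))
  pts <- contour_points(gen$contour)
  sp <- efd_transform(gen$contour)
  rc <- contour_points(efd_reconstruct(sp))
  nn <- vapply(seq(1, nrow(rc), by = 7), function(i)
    min(sqrt((pts[, 1] - rc[i, 1])^2 + (pts[, 2] - rc[i, 2])^2)), numeric(1))
  expect_lt(mean(nn), 1)
  expect_error(efd_reconstruct(sp, bands = character(0)), "empty band")
})

test_that("Delta carries the outline and Alpha the serration of a 30-tooth leaflet", {
  gen <- make_leaflet_contour(leaflet_spec(tooth_count = 30, toothed_arc = 0.7,
                                           tooth_height = 10, seed = 2))
  b <- blade_of(gen)
  sp <- efd_transform(b$record$contour)
  expect_equal(count_teeth(efd_reconstruct(sp, bands = "delta"), b$junction), 0)
  da <- count_teeth(efd_reconstruct(sp, bands = c("delta", "alpha")), b$junction)
  expect_gte(da, 29); expect_lte(da, 31)
})

test_that("truncation residual power is non-increasing in the cutoff harmonic", {
  for (seed in c(3, 8)) {
    gen <- make_leaflet_contour(leaflet_spec(tooth_count = 18, seed = seed))
    pts <- contour_points(gen$contour)
    sp <- efd_transform(gen$contour)
    res <- vapply(c(5, 19, 55, 120), function(k) {
      rc <- contour_points(efd_reconstruct(sp, harmonics = seq_len(k)))
      mean(vapply(seq(1, nrow(rc), by = 17), function(i)
        min(sqrt((pts[, 1] - rc[i, 1])^2 + (pts[, 2] - rc[i, 2])^2)), numeric(1)))
    }, numeric(1))
    expect_true(all(diff(res) <= 1e-9))
  }
})

test_that("the low-pass filter removes hair spikes, is near-identity at high cutoff, and matches Delta", {
  gen <- make_leaflet_contour(leaflet_spec(tooth_count = 12, margin_noise_sd = 0, seed = 6))
  b <- blade_of(gen)
  pts <- contour_points(b$record$contour)
  # add 1-2 px hair spikes normal to the margin
  spiky <- pts
  at <- seq(20, nrow(pts) - 20, by = 97)
  cen <- leafletkit:::polygon_centroid(pts)
  for (i in at) {
    v <- pts[i, ] - cen
    spiky[i, ] <- pts[i, ] + 2 * v / sqrt(sum(v^2))
  }
  filt <- lowpass_outline_filter(leaf_contour(spiky), 120)
  expect_equal(count_teeth(filt, b$junction), 12)   # hairless ground-truth count

  # near identity when the cutoff reaches half the point count
  lp <- lowpass_outline_filter(gen$contour, ceiling(nrow(pts) / 2))
  p2 <- contour_points(lp)
  full <- contour_points(gen$contour)
  nn <- vapply(seq(1, nrow(p2), by = 11), function(i)
    min(sqrt((full[, 1] - p2[i, 1])^2 + (full[, 2] - p2[i, 2])^2)), numeric(1))
  expect_lt(mean(nn), 0.5)

  # cutoff 19 reproduces the Delta-band reconstruction exactly
  expect_equal(contour_points(lowpass_outline_filter(gen$contour, 19)),
               contour_points(efd_reconstruct(efd_transform(gen$contour), bands = "delta")),
               tolerance = 1e-12)
  expect_error(lowpass_outline_filter(gen$contour, 0), ">= 1")
})

test_that("half-power frequency decreases from young to old node groups", {
  # many small teeth push spectral weight upward; the node series L1 -> L6
  # must show monotonically decreasing group-mean half-power frequency
  feats <- preset_features("heteroblasty6")
  mhpf <- tapply(feats$half_power_frequency, feats$group, mean)
  expect_true(all(diff(mhpf[paste0("L", 1:6)]) < 0))
})
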