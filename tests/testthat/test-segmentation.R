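# Boundary tracing, radial profiles, junction detection and leaflet
# separation.

test_that("trace_contour follows known boundaries with positive orientation", {
  m <- matrix(FALSE, 14, 14); m[3:12, 3:12] <- TRUE
  ct <- trace_contour(m)
  expect_equal(nrow(contour_points(ct)), 36)      # boundary pixels of a 10x10 square
  expect_gt(leafletkit:::shoelace_area(contour_points(ct)), 0)

  ct2 <- trace_contour(disk_mask(50))
  per <- leafletkit:::chain_perimeter(contour_points(ct2))
  expect_lt(abs(per - 2 * pi * 50) / (2 * pi * 50), 0.05)

  expect_error(trace_contour(matrix(FALSE, 5, 5)), "empty")
  two <- matrix(FALSE, 20, 20); two[2:5, 2:5] <- TRUE; two[12:15, 12:15] <- TRUE
  expect_error(trace_contour(two), "2 connected components")
})

test_that("radial_profile matches constant-radius, corner and translation oracles", {
  circ <- ellipse_contour(60)
  pr <- radial_profile(circ)
  expect_true(all(pr$distances > 59 & pr$distances < 61))

  sq <- square_contour(100)
  prs <- radial_profile(sq)
  expect_lt(abs(max(prs$distances) - 100 * sqrt(2) / 2), 1)  # exact corner distance

  shifted <- leaf_contour(sweep(contour_points(sq), 2, c(-17, 5)))
  prt <- radial_profile(shifted)
  expect_equal(prt$distances, prs$distances, tolerance = 1e-12)
  expect_equal(prt$centroid, prs$centroid + c(17, -5), tolerance = 1e-9)
})

test_that("find_junction recovers generator junctions and rejects stalk-less shapes", {
  for (s in 1:3) {
    gen <- make_leaflet_contour(leaflet_spec(tooth_count = 12, seed = s))
    j <- find_junction(radial_profile(gen$contour))
    gap <- abs(sort(j) - sort(gen$truth$junction_indices))
    n <- nrow(gen$contour)
    expect_true(all(pmin(gap, n - gap) <= 3))
  }
  expect_error(find_junction(radial_profile(ellipse_contour(100, 60))), "no junction")
})

test_that("the depth threshold never selects a sinus bottom as a junction", {
  # sinus depth ~10% of radius, junction indentation ~70%: all sinus minima
  # stay above depth_fraction * median (oracle: direct comparison of every
  # profile minimum against the threshold)
  gen <- make_leaflet_contour(leaflet_spec(base_a = 100, base_b = 90,
                                           tooth_count = 14, tooth_height = 10,
                                           junction_depth = 0.7, seed = 4))
  pr <- radial_profile(gen$contour)
  j <- find_junction(pr, depth_fraction = 0.5)
  pts <- contour_points(gen$contour)
  tips <- gen$truth$tooth_tips
  # every returned junction point is near the true junction, far from any sinus
  for (idx in j) {
    dj <- sqrt(sum((pts[idx, ] - gen$truth$junction_midpoint)^2))
    expect_lt(dj, 15)
  }
  d <- pr$distances
  thr <- 0.5 * median(leafletkit:::circ_ma(d, 5))
  # oracle: the sinus region (margin between teeth) never dips below the threshold
  sin_r <- min(apply(tips, 1, function(p) sqrt(sum(p^2)))) - 10
  expect_gt(sin_r, thr)
})

test_that("separate_leaflets yields three correctly labelled blades with accurate areas", {
  r <- trifoliate_fixture()
  mask <- segment_foreground(r$image, "dark")
  recs <- separate_leaflets(mask)
  expect_length(recs, 3)
  expect_setequal(vapply(recs, `[[`, character(1), "role"), r$truth$roles)
  total <- sum(mask_pixels(mask))
  areas <- vapply(recs, function(rec) leafletkit:::contour_area(rec$contour), numeric(1))
  expect_lt(sum(areas), total)          # stalk pixels excluded
  for (rec in recs) {
    gt <- r$truth$blade_areas[match(rec$role, r$truth$roles)]
    expect_lt(abs(leafletkit:::contour_area(rec$contour) - gt) / gt, 0.02)
    expect_gt(leafletkit:::shoelace_area(contour_points(rec$contour)), 0)
  }
  expect_error(separate_leaflets(binary_mask(disk_mask(50))), "expected 3")
})

test_that("junction detection is equivariant under a 90-degree image rotation", {
  r <- trifoliate_fixture()
  mask <- segment_foreground(r$image, "dark")
  recs <- separate_leaflets(mask)
  m <- mask_pixels(mask)
  H <- nrow(m)
  m90 <- t(m)[, H:1]                    # (x, y) -> (H-1-y, x)
  recs90 <- separate_leaflets(binary_mask(m90))
  for (rec in recs) {
    mapped <- c(H - 1 - rec$junction_midpoint[2], rec$junction_midpoint[1])
    best <- min(vapply(recs90, function(q)
      sqrt(sum((q$junction_midpoint - mapped)^2)), numeric(1)))
    expect_lte(best, 4)
  }
})

test_that("manual sidecar junctions override detection", {
  r <- trifoliate_fixture()
  mask <- segment_foreground(r$image, "dark")
  recs <- separate_leaflets(mask, junctions = r$truth$junctions)
  expect_length(recs, 3)
  for (rec in recs) {
    gt <- r$truth$blade_areas[match(rec$role, r$truth$roles)]
    expect_lt(abs(leafletkit:::contour_area(rec$contour) - gt) / gt, 0.02)
  }
})
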