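# Image loading, background segmentation, trichome removal, scan splitting.

test_that("load_scan reads PNG/TIFF, applies the dpi fallback chain, and errors on bad paths", {
  px <- array(runif(100 * 120 * 3), dim = c(100, 120, 3))
  png_path <- withr::local_tempfile(fileext = ".png")
  png::writePNG(px, png_path)
  img <- load_scan(png_path)
  expect_equal(dim(img$pixels)[1:2], c(100, 120))
  expect_equal(img$dpi, 800)          # no metadata, no override: scanner default
  expect_equal(load_scan(png_path, dpi_override = 300)$dpi, 300)

  tif_path <- withr::local_tempfile(fileext = ".tif")
  tiff::writeTIFF(px, tif_path)
  expect_equal(dim(load_scan(tif_path)$pixels)[1:2], c(100, 120))

  # grayscale replicated to three channels
  gray_path <- withr::local_tempfile(fileext = ".png")
  png::writePNG(matrix(runif(50 * 60), 50, 60), gray_path)
  expect_equal(dim(load_scan(gray_path)$pixels), c(50, 60, 3))

  expect_error(load_scan(file.path(tempdir(), "no-such-file.png")), "not found")
  bad <- withr::local_tempfile(fileext = ".txt")
  writeLines("x", bad)
  expect_error(load_scan(bad), "unsupported")
})

test_that("segment_foreground recovers a disk against dark and gray fields", {
  r <- 80
  m <- disk_mask(r)
  sz <- nrow(m)
  for (bg in c("dark", "gray")) {
    bgcol <- if (bg == "dark") c(15, 15, 15) else c(128, 128, 128)
    px <- array(rep(bgcol, each = sz * sz), dim = c(sz, sz, 3))
    idx <- which(m, arr.ind = TRUE)
    for (ch in 1:3) px[cbind(idx, ch)] <- c(40, 140, 40)[ch]
    mask <- segment_foreground(raster_image(px), background = bg)
    # oracle: count of pixels inside the analytic disk
    expect_lt(abs(sum(mask_pixels(mask)) - sum(m)) / sum(m), 0.01)
    expect_lt(abs(sum(m) - pi * r^2) / (pi * r^2), 0.01)
  }
})

test_that("segment_foreground errors on empty scenes and keeps disjoint leaves in one mask", {
  black <- raster_image(array(10, dim = c(60, 60, 3)))
  expect_error(segment_foreground(black, "gray"), "no leaf found")

  sz <- 200
  px <- array(12, dim = c(sz, sz, 3))
  two <- disk_mask(40, pad = 10)
  for (ch in 1:3) {
    sub <- px[1:100, 1:100, ch]; sub[two] <- c(40, 140, 40)[ch]; px[1:100, 1:100, ch] <- sub
    sub <- px[101:200, 101:200, ch]; sub[two] <- c(40, 140, 40)[ch]; px[101:200, 101:200, ch] <- sub
  }
  mask <- segment_foreground(raster_image(px), "dark")
  expect_equal(max(EBImage::bwlabel(mask_pixels(mask) * 1L)), 2)  # both kept in one mask
})

test_that("the YCbCr chroma rule removes gray trichome pixels and keeps green tissue", {
  # oracle: direct BT.601 conversion of both triples
  yc_gray <- leafletkit:::rgb_to_ycbcr(200, 200, 200)
  yc_green <- leafletkit:::rgb_to_ycbcr(40, 140, 40)
  expect_true(abs(yc_gray$cb - 128) < 12 && abs(yc_gray$cr - 128) < 12 && yc_gray$y > 120)
  expect_false(abs(yc_green$cb - 128) < 12 && abs(yc_green$cr - 128) < 12 && yc_green$y > 120)

  # a green block with a single 2-px-wide gray stroke: stroke removed, block kept
  px <- array(15, dim = c(70, 70, 3))
  for (ch in 1:3) px[20:55, 20:55, ch] <- c(40, 140, 40)[ch]
  for (ch in 1:3) px[10:20, 30:31, ch] <- 200
  img <- raster_image(px)
  mask <- segment_foreground(img, "dark")
  out <- remove_trichomes(img, mask)
  expect_true(all(mask_pixels(out)[21:55, 20:55]))
  expect_false(any(mask_pixels(out)[10:19, 30:31]))

  # trichome-free input is returned unchanged
  px2 <- array(15, dim = c(50, 50, 3))
  for (ch in 1:3) px2[10:40, 10:40, ch] <- c(40, 140, 40)[ch]
  img2 <- raster_image(px2)
  m2 <- segment_foreground(img2, "dark")
  expect_identical(mask_pixels(remove_trichomes(img2, m2)), mask_pixels(m2))
})

test_that("trichome removal restores the hairless leaf area and spares the blade interior", {
  r <- trifoliate_fixture(trichomes = 60, seed = 9)
  mask <- segment_foreground(r$image, "dark")
  clean <- remove_trichomes(r$image, mask)
  hairless <- sum(r$truth$hairless_mask)
  expect_lt(abs(sum(mask_pixels(clean)) - hairless) / hairless, 0.02)
  # interior of the hairless blades is never removed
  interior <- EBImage::erode(r$truth$hairless_mask * 1L,
                             EBImage::makeBrush(9, "disc")) > 0
  expect_true(all(mask_pixels(clean)[interior]))
})

test_that("split_leaves returns per-leaf masks in row-major arrangement order", {
  sz <- 330
  m <- matrix(FALSE, 240, sz)
  d <- disk_mask(30, pad = 5)
  at <- list(c(1, 1), c(1, 110), c(1, 230), c(130, 1), c(130, 110), c(130, 230))
  for (p in at) m[p[1]:(p[1] + 69), p[2]:(p[2] + 69)] <- m[p[1]:(p[1] + 69), p[2]:(p[2] + 69)] | d
  leaves <- split_leaves(binary_mask(m))
  expect_length(leaves, 6)
  # oracle: sort of the known bounding boxes (row band, then column)
  centres <- t(vapply(leaves, function(l) {
    w <- which(mask_pixels(l), arr.ind = TRUE); c(mean(w[, 1]), mean(w[, 2]))
  }, numeric(2)))
  expect_true(all(diff(centres[1:3, 2]) > 0))
  expect_true(all(diff(centres[4:6, 2]) > 0))
  expect_true(all(centres[1:3, 1] < centres[4, 1]))

  expect_length(split_leaves(binary_mask(matrix(FALSE, 10, 10))), 0)
  one <- split_leaves(binary_mask(disk_mask(30)))
  expect_length(one, 1)
  expect_identical(mask_pixels(one[[1]]), disk_mask(30))
})
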