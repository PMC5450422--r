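# Reading scanned leaf images, foreground segmentation against dark or gray
# scanner backgrounds, YCbCr trichome removal, and multi-leaf scan splitting.

#' Raster image constructor
#'
#' @param pixels H x W x 3 array of RGB values in 0..255, or H x W matrix
#'   (grayscale, replicated to 3 channels)
#' @param dpi dots per inch; used only for the pixel-to-mm conversion
#'   mm = px * 25.4 / dpi at export time
#' @return object of class `raster_image`
#' @export
raster_image <- function(pixels, dpi = 800) {
  if (is.matrix(pixels)) pixels <- array(rep(pixels, 3), dim = c(dim(pixels), 3))
  stopifnot(length(dim(pixels)) == 3, dim(pixels)[3] >= 3, dpi > 0)
  structure(list(pixels = pixels[, , 1:3, drop = FALSE], dpi = dpi),
            class = "raster_image")
}

#' @export
print.raster_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<raster_image> %d x %d px, %g dpi\n", d[1], d[2], x$dpi))
  invisible(x)
}

#' Binary mask constructor
#' @param pixels logical H x W matrix, TRUE = leaf tissue
#' @param dpi inherited resolution
#' @export
binary_mask <- function(pixels, dpi = 800) {
  stopifnot(is.matrix(pixels))
  structure(list(pixels = pixels > 0, dpi = dpi), class = "binary_mask")
}

#' Logical pixel matrix of a mask (accepts plain logical matrices too)
#' @export
mask_pixels <- function(mask) {
  if (inherits(mask, "binary_mask")) mask$pixels else mask > 0
}

# dpi of a mask or image, with the acquisition default as fallback
obj_dpi <- function(x, default = 800) {
  d <- if (is.list(x)) x$dpi else NULL
  if (is.null(d) || !is.finite(d)) default else d
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask> %d x %d px, %d foreground px\n",
              nrow(x$pixels), ncol(x$pixels), sum(x$pixels)))
  invisible(x)
}

#' Load a scanned leaf image from TIFF or PNG
#'
#' Resolution is taken from the file metadata when present, otherwise from
#' `dpi_override`, otherwise the 800 dpi acquisition default is assumed.
#'
#' @param path path to a TIFF or PNG file
#' @param dpi_override optional dpi used when the file carries none
#' @return a `raster_image`
#' @export
load_scan <- function(path, dpi_override = NULL) {
  if (!file.exists(path)) stop("cannot read image: file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  dpi <- NA_real_
  if (ext %in% c("tif", "tiff")) {
    img <- tiff::readTIFF(path, info = TRUE)
    xres <- attr(img, "x.resolution")
    unit <- attr(img, "resolution.unit")
    if (!is.null(xres) && is.finite(xres) && xres > 0) {
      dpi <- if (identical(unit, "cm")) xres * 2.54 else xres
    }
  } else if (ext == "png") {
    img <- png::readPNG(path, info = TRUE)
    info <- attr(img, "info")
    if (!is.null(info$dpi) && all(is.finite(info$dpi))) dpi <- info$dpi[1]
  } else stop("unsupported image format: ", ext)
  if (!is.finite(dpi) || dpi <= 0)
    dpi <- if (!is.null(dpi_override)) dpi_override else 800
  px <- img
  attributes(px) <- list(dim = dim(img))
  if (length(dim(px)) == 2) px <- array(rep(px, 3), dim = c(dim(px), 3))
  raster_image(px[, , 1:3, drop = FALSE] * 255, dpi = dpi)
}

#' Export a binary mask as a PNG file (white = foreground), for audit
#' @param mask a `binary_mask`
#' @param path output path
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(mask_pixels(mask) * 1, path)
  invisible(path)
}

# BT.601 full-range RGB -> YCbCr
rgb_to_ycbcr <- function(r, g, b) {
  list(y  = 0.299 * r + 0.587 * g + 0.114 * b,
       cb = 128 - 0.168736 * r - 0.331264 * g + 0.5 * b,
       cr = 128 + 0.5 * r - 0.418688 * g - 0.081312 * b)
}

# Otsu threshold on a numeric matrix scaled to 0..1
otsu_threshold <- function(v) {
  EBImage::otsu(EBImage::Image(v / 255), range = c(0, 1), levels = 256) * 255
}

#' Segment leaf tissue from the scanner background
#'
#' Two background models match the acquisition protocol: leaves scanned
#' against a dark field are separated by an Otsu threshold on luminance;
#' against a gray field, by green dominance (G - max(R, B) above a fixed
#' offset, which a neutral gray background cannot satisfy). Holes inside
#' leaves are filled and sub-threshold specks removed.
#'
#' @param img a `raster_image`
#' @param background `"dark"` or `"gray"`
#' @param min_area components below this area (px^2) are dropped as dust
#' @param green_offset threshold for the gray-background green-dominance rule
#' @return a `binary_mask`
#' @export
segment_foreground <- function(img, background = c("dark", "gray"),
                               min_area = 500, green_offset = 20) {
  background <- match.arg(background)
  px <- img$pixels
  r <- px[, , 1]; g <- px[, , 2]; b <- px[, , 3]
  fg <- if (background == "dark") {
    y <- 0.299 * r + 0.587 * g + 0.114 * b
    y > otsu_threshold(y)
  } else {
    (g - pmax(r, b)) > green_offset
  }
  if (!any(fg)) stop("no leaf found: segmentation produced an empty mask")
  fg <- EBImage::fillHull(fg * 1L) > 0
  lab <- EBImage::bwlabel(fg * 1L)
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_area)
  fg <- matrix(lab %in% keep, nrow(fg), ncol(fg))
  if (!any(fg)) stop("no leaf found: all components below the minimum area")
  binary_mask(fg, dpi = img$dpi)
}

#' Remove trichomes from a leaf mask by YCbCr chroma analysis
#'
#' Trichomes appear as thin, grayish-white strokes: nearly neutral chroma
#' (Cb and Cr close to 128) at high luma, unlike the green blade tissue.
#' Matching pixels are removed from the mask only when they form thin
#' structures (inscribed width at most `max_trichome_width` px), which
#' protects pale blade regions.
#'
#' @param img the source `raster_image`
#' @param mask `binary_mask` aligned with `img`
#' @param cb_tol,cr_tol chroma neutrality tolerances around 128
#' @param y_min minimum luma for the trichome model
#' @param max_trichome_width maximum width (px) of structures removed
#' @return a `binary_mask` with trichome pixels removed
#' @export
remove_trichomes <- function(img, mask, cb_tol = 12, cr_tol = 12, y_min = 120,
                             max_trichome_width = 5) {
  m <- mask_pixels(mask)
  px <- img$pixels
  yc <- rgb_to_ycbcr(px[, , 1], px[, , 2], px[, , 3])
  cand <- m & abs(yc$cb - 128) < cb_tol & abs(yc$cr - 128) < cr_tol & yc$y > y_min
  if (!any(cand)) return(binary_mask(m, dpi = obj_dpi(mask)))
  lab <- EBImage::bwlabel(cand * 1L)
  dm <- EBImage::distmap(cand * 1L)
  nmax <- max(lab)
  wmax <- rep(0, nmax)
  idx <- which(lab > 0)
  wtab <- tapply(dm[idx], lab[idx], max)
  wmax[as.integer(names(wtab))] <- wtab
  thin <- which(2 * wmax <= max_trichome_width)
  out <- m & !(matrix(lab %in% thin, nrow(m), ncol(m)))
  # a hair crossing a thin stalk leaves a 1-3 px break when removed; a
  # small morphological closing re-seals tissue without moving the margin
  out <- EBImage::closing(out * 1L, EBImage::makeBrush(5, "disc")) > 0
  binary_mask(out, dpi = obj_dpi(mask))
}

#' Split a multi-leaf scan mask into per-leaf masks
#'
#' One mask per connected component above the minimum area, ordered by
#' bounding-box position row-major (top-to-bottom bands, then left-to-right)
#' so that the physical arrangement of leaves L1..Ln on the scanner bed maps
#' to list order.
#'
#' @param mask `binary_mask` of a whole scan
#' @param min_area minimum component area (px^2)
#' @return list of `binary_mask`, possibly empty
#' @export
split_leaves <- function(mask, min_area = 500) {
  m <- mask_pixels(mask)
  if (!any(m)) return(list())
  lab <- EBImage::bwlabel(m * 1L)
  sizes <- tabulate(lab[lab > 0])
  ids <- which(sizes >= min_area)
  if (!length(ids)) return(list())
  boxes <- t(vapply(ids, function(k) {
    w <- which(lab == k, arr.ind = TRUE)
    c(ymin = min(w[, 1]), xmin = min(w[, 2]), h = diff(range(w[, 1])) + 1)
  }, numeric(3)))
  # band rows: components whose top edges differ by less than half the median
  # height belong to the same row of the arrangement
  ord <- order(boxes[, 1])
  band <- numeric(length(ids))
  cur <- 1
  band[ord[1]] <- 1
  tol <- stats::median(boxes[, 3]) / 2
  for (k in seq_along(ord)[-1]) {
    if (boxes[ord[k], 1] - boxes[ord[k - 1], 1] > tol) cur <- cur + 1
    band[ord[k]] <- cur
  }
  final <- order(band, boxes[, 2])
  lapply(ids[final], function(k)
    binary_mask(matrix(lab == k, nrow(m), ncol(m)), dpi = obj_dpi(mask)))
}
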