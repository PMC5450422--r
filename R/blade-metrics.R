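# Blade length, width, area, perimeter and shape parameters of a separated
# leaflet, including the manual curved-midvein length mode.

#' Blade length of a leaflet
#'
#' The distance d_i from the junction midpoint (x0, y0) to every margin
#' point (x_i, y_i) is computed and the blade length is the longest,
#' L = max_i d_i. The arg-max margin point (the blade tip) defines the
#' length axis together with the junction midpoint.
#'
#' @param record a `leaflet_record`
#' @return list(L, tip = tip coordinates, tip_index)
#' @export
blade_length <- function(record) {
  pts <- contour_points(record$contour)
  if (nrow(pts) < 3) stop("degenerate contour: fewer than 3 points")
  x0 <- record$junction_midpoint
  d <- sqrt((pts[, 1] - x0[1])^2 + (pts[, 2] - x0[2])^2)
  i <- which.max(d)
  list(L = d[i], tip = pts[i, ], tip_index = i)
}

#' Blade length along a manually supplied curved midvein
#'
#' When a leaflet's midvein is curved, three or more control points on the
#' midvein (ordered base to tip) define a natural cubic interpolating curve
#' through the junction midpoint, the control points and the blade tip; the
#' blade length is the arc length of that curve.
#'
#' @param record a `leaflet_record`
#' @param midvein_points matrix of >= 3 (x, y) control points, ordered
#'   base to tip
#' @param n_eval sampling resolution of the arc-length integral
#' @return list(L, curve = sampled curve points)
#' @export
blade_length_curved <- function(record, midvein_points, n_eval = 2000) {
  mv <- as.matrix(midvein_points)
  if (nrow(mv) < 3) stop("need at least 3 midvein control points")
  base <- record$junction_midpoint
  tip <- blade_length(record)$tip
  ctrl <- rbind(base, mv, tip)
  # monotonicity along the base->tip axis guards against unordered input
  ax <- tip - base
  proj <- as.numeric((ctrl[, 1] - base[1]) * ax[1] + (ctrl[, 2] - base[2]) * ax[2])
  if (any(diff(proj) <= 0)) stop("midvein control points must be ordered from base to tip")
  s <- c(0, cumsum(sqrt(rowSums(diff(ctrl)^2))))
  fx <- stats::splinefun(s, ctrl[, 1], method = "natural")
  fy <- stats::splinefun(s, ctrl[, 2], method = "natural")
  ss <- seq(0, max(s), length.out = n_eval)
  curve <- cbind(fx(ss), fy(ss))
  list(L = sum(sqrt(rowSums(diff(curve)^2))), curve = curve)
}

#' Blade width orthogonal to the length axis
#'
#' Chords orthogonal to the blade length axis are erected at stations spaced
#' `spacing` px along it (5 px, giving floor(L/5) + 1 stations); each
#' station's chord is the longest single in-blade crossing of the margin, so
#' sinuses on a concave margin do not inflate the width. W is the longest
#' chord; ties go to the station nearest the blade base. A curved axis from
#' [blade_length_curved()] may be supplied; chords are then orthogonal to
#' the local tangent.
#'
#' @param record a `leaflet_record`
#' @param axis optional curve matrix (defaults to the straight base-tip
#'   segment)
#' @param spacing station spacing along the axis in px (default 5; 1 gives
#'   the brute-force mode used as a test oracle)
#' @return list(W, chord = 2 x 2 matrix of chord endpoints, station_index,
#'   n_stations)
#' @export
blade_width <- function(record, axis = NULL, spacing = 5) {
  pts <- contour_points(record$contour)
  if (is.null(axis)) {
    bl <- blade_length(record)
    axis <- rbind(record$junction_midpoint, bl$tip)
  }
  axis <- as.matrix(axis)
  seg <- sqrt(rowSums(diff(axis)^2))
  s <- c(0, cumsum(seg))
  L <- max(s)
  n_st <- floor(L / spacing) + 1
  st <- pmin((seq_len(n_st) - 1) * spacing, L)
  sx <- stats::approx(s, axis[, 1], xout = st)$y
  sy <- stats::approx(s, axis[, 2], xout = st)$y
  # local tangent by central differences along the axis
  tx <- stats::approx(s, axis[, 1], xout = pmin(st + 1, L))$y -
    stats::approx(s, axis[, 1], xout = pmax(st - 1, 0))$y
  ty <- stats::approx(s, axis[, 2], xout = pmin(st + 1, L))$y -
    stats::approx(s, axis[, 2], xout = pmax(st - 1, 0))$y
  best <- 0; best_i <- NA; best_chord <- NULL
  for (k in seq_len(n_st)) {
    tv <- c(tx[k], ty[k])
    nv <- c(-tv[2], tv[1])
    nv <- nv / sqrt(sum(nv^2))
    ch <- line_polygon_chords(pts, c(sx[k], sy[k]), nv)$chords
    if (!nrow(ch)) next
    w <- max(ch[, "len"])
    if (w > best + 1e-9) {          # strict improvement: ties keep the
      best <- w                     # earlier (base-nearest) station
      best_i <- k
      t2 <- ch[which.max(ch[, "len"]), ]
      best_chord <- rbind(c(sx[k], sy[k]) + t2["t1"] * nv,
                          c(sx[k], sy[k]) + t2["t2"] * nv)
    }
  }
  if (best <= 0) stop("no width chord intersects the contour")
  list(W = best, chord = best_chord, station_index = best_i, n_stations = n_st)
}

#' Blade shape parameter set
#'
#' Area (enclosed contour area), perimeter, length/width ratio, leaflet
#' symmetry (ratio of blade area left vs right of the length axis) and
#' compactness 4*pi*A/P^2 (1 for a circle, capped at 1 against sub-percent
#' digitization bias).
#'
#' @param record a `leaflet_record`
#' @param L,W blade length/width; computed when missing
#' @return object of class `blade_metrics`: list(length, width, area,
#'   perimeter, length_width_ratio, symmetry, compactness, tip)
#' @export
blade_shape_params <- function(record, L = NULL, W = NULL) {
  pts <- contour_points(record$contour)
  bl <- blade_length(record)
  if (is.null(L)) L <- bl$L
  if (is.null(W)) W <- blade_width(record)$W
  area <- contour_area(record$contour)
  per <- chain_perimeter(pts)
  base <- record$junction_midpoint
  tip <- bl$tip
  aL <- abs(shoelace_area(clip_halfplane(pts, base, tip, side = 1)))
  aR <- abs(shoelace_area(clip_halfplane(pts, base, tip, side = -1)))
  structure(list(length = L, width = W, area = area, perimeter = per,
                 length_width_ratio = L / W,
                 symmetry = if (aR > 0) aL / aR else NA_real_,
                 compactness = min(1, 4 * pi * area / per^2),
                 tip = tip),
            class = "blade_metrics")
}

#' @export
print.blade_metrics <- function(x, ...) {
  cat(sprintf("<blade_metrics> L=%.1f W=%.1f px, area=%.0f px^2, L/W=%.2f, symmetry=%.2f, compactness=%.3f\n",
              x$length, x$width, x$area, x$length_width_ratio, x$symmetry, x$compactness))
  invisible(x)
}
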