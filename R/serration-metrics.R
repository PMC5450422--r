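# Detection of serration (tooth) tips and sinus (valley) bottoms on the
# leaflet margin, per-tooth and per-valley geometry, and the aggregated
# margin parameter set (tooth base line, outer/inner toothed areas, inner
# blade area and perimeter, and the derived ratios).

#' Detect tooth tips and sinus bottoms on a radial profile
#'
#' Tooth tips are margin points with locally maximal centroid distance under
#' the strict 5-point rule d_i > d_(i+1) > d_(i+2) and d_i > d_(i-1) >
#' d_(i-2); sinus bottoms use the mirrored inequalities. The rule is applied
#' after plateau collapse and light smoothing; extrema whose topographic
#' prominence falls below `min_prominence` are discarded (the raw rule alone
#' fires on pixel noise), and tips/valleys are forced to interleave by
#' keeping the highest tip / lowest valley of any same-type run.
#'
#' @param profile a [radial_profile()] of a separated leaflet
#' @param min_prominence prominence threshold in px; default
#'   1.5 + 2% of the median centroid distance
#' @param exclude contour indices excluded from the search (the junction
#'   arc, so the blade base is never a "valley")
#' @param smooth_window moving-average window for the extremum test (the raw
#'   profile is kept for geometry)
#' @param baseline_window_px circular running-median window, in px of
#'   margin arc, removing the slow radial trend of the blade outline before
#'   the extremum and prominence tests; the trend would otherwise mask the
#'   relief of teeth on oblique flanks. The default (40 px) sits between
#'   the tooth scale and the outline scale.
#' @param baseline_window explicit window in contour samples (overrides
#'   `baseline_window_px`)
#' @return list(tips, valleys): contour indices, interleaved
#' @export
detect_extrema <- function(profile, min_prominence = NULL, exclude = NULL,
                           smooth_window = 5, baseline_window_px = 40,
                           baseline_window = NULL) {
  d <- profile$distances
  n <- length(d)
  if (is.null(min_prominence)) min_prominence <- 1.5 + 0.02 * stats::median(d)
  # the strict 5-point rule assumes pixel-chain granularity (~1 px steps);
  # oversampled polygon contours are decimated toward that scale first, or
  # tip plateaus defeat the strict inequalities
  pts <- contour_points(profile$contour)
  step <- polyline_length(pts, closed = TRUE) / n
  dec <- max(1L, as.integer(floor(1 / step)))
  if (step * dec < 0.75) dec <- dec + 1L
  idx0 <- seq(1L, n, by = dec)
  cp <- collapse_plateaus(d[idx0])
  cp$index <- idx0[cp$index]
  ds <- circ_ma(cp$values, smooth_window)
  m <- length(ds)
  if (is.null(baseline_window))
    baseline_window <- max(31, round(baseline_window_px / (step * dec)))
  dd <- ds - circ_ma(ds, min(baseline_window, m))
  ex <- extrema_5pt(dd, circular = TRUE)
  tip_cand <- ex$max
  if (length(tip_cand)) {
    pr <- peak_prominence(dd, tip_cand, circular = TRUE)
    tip_cand <- tip_cand[pr >= min_prominence]
  }
  tips <- cp$index[tip_cand]
  circular <- is.null(exclude) || !length(exclude)
  if (!circular) tips <- setdiff(tips, exclude)
  tips <- sort(tips)
  if (!length(tips)) return(list(tips = integer(0), valleys = integer(0)))
  # sinus bottoms: the deepest margin point between consecutive accepted
  # tips (plus, on a junction-broken margin, the deepest point between the
  # junction gap and the first/last tooth). Constructing valleys from the
  # accepted tips guarantees strict tip/valley interleaving even where a
  # flat sinus floor makes the raw 5-point rule noise-brittle.
  allowed <- if (circular) rep(TRUE, n) else !(seq_len(n) %in% exclude)
  argmin_between <- function(a, b) {
    span <- if (a <= b) a:b else c(a:n, 1:b)
    span <- span[allowed[span]]
    span <- setdiff(span, c(a, b))
    if (!length(span)) return(NA_integer_)
    span[which.min(d[span])]
  }
  valleys <- integer(0)
  if (length(tips) >= 2) {
    for (i in seq_len(length(tips) - 1))
      valleys <- c(valleys, argmin_between(tips[i], tips[i + 1]))
  }
  if (circular) {
    valleys <- c(valleys, argmin_between(tips[length(tips)], tips[1]))
  } else {
    # boundary sinuses between the junction gap and the outermost teeth
    gap <- sort(exclude)
    after_gap <- gap[length(gap)]
    before_gap <- gap[1]
    valleys <- c(argmin_between(after_gap, tips[1]), valleys,
                 argmin_between(tips[length(tips)], before_gap))
  }
  valleys <- sort(unique(valleys[!is.na(valleys)]))
  list(tips = tips, valleys = valleys)
}

#' Contour indices of the junction arc of a separated blade
#'
#' Margin points belonging to the blade-stalk junction region: points near
#' the junction chord plus the angular sector (seen from the blade centroid)
#' that the junction cut subtends, padded. Excluding these from the
#' extremum search keeps the blade base and its cut corners from being
#' scored as teeth or sinuses.
#'
#' @param contour blade `leaf_contour`
#' @param junction_endpoints 2 x 2 matrix of junction point coordinates
#' @param pad_px radial padding of the sector (px)
#' @param pad_steps index padding added around matched points
#' @return integer contour indices (possibly empty)
#' @export
junction_arc_indices <- function(contour, junction_endpoints, pad_px = 10,
                                 pad_steps = 8) {
  pts <- contour_points(contour)
  n <- nrow(pts)
  je <- matrix(as.numeric(junction_endpoints), 2, 2)
  jm <- colMeans(je)
  cen <- polygon_centroid(pts)
  v <- jm - cen
  dj <- sqrt(sum(v^2))
  chord <- sqrt(sum((je[1, ] - je[2, ])^2))
  halfw <- asin(min(0.95, (chord / 2 + pad_px) / max(dj, 1e-6)))
  ang <- atan2(pts[, 2] - cen[2], pts[, 1] - cen[1])
  aj <- atan2(v[2], v[1])
  dd <- atan2(sin(ang - aj), cos(ang - aj))
  sector <- abs(dd) <= halfw
  near_chord <- dist_point_line(pts, je[1, ], je[2, ]) < 4 &
    sqrt((pts[, 1] - jm[1])^2 + (pts[, 2] - jm[2])^2) < chord / 2 + pad_px
  idx <- which(sector | near_chord)
  if (length(idx)) idx <- unique(sort((as.integer(outer(idx, -pad_steps:pad_steps, "+")) - 1) %% n + 1))
  idx
}

# flanking neighbours of index i within sorted vector v (along the contour);
# wrap allowed only when wrap = TRUE
flank <- function(i, v, n, wrap) {
  lo <- v[v < i]; hi <- v[v > i]
  left <- if (length(lo)) max(lo) else if (wrap && length(v)) max(v) else NA
  right <- if (length(hi)) min(hi) else if (wrap && length(v)) min(v) else NA
  c(left, right)
}

# contour indices from a to b forward (possibly wrapping)
arc_indices <- function(a, b, n) if (a <= b) a:b else c(a:n, 1:b)

#' Per-tooth geometry
#'
#' For each tooth, a connection line joins the two flanking sinus bottoms
#' (the tooth base); tooth height is the perpendicular distance from the tip
#' to that line, tooth area the shoelace area enclosed by the real margin
#' arc and the base, tooth perimeter the arc plus base length, and the three
#' tooth angles come from the tip / left-valley / right-valley triangle.
#' Teeth whose margin arc exceeds 10x the median tooth arc, or a quarter of
#' the whole contour, are rejected as broken-margin artifacts or outline
#' swells (logged via warning for sidecar review).
#'
#' @param contour a `leaf_contour`
#' @param tips,valleys interleaved indices from [detect_extrema()]
#' @param circular allow flanking across the contour start (NULL: only when
#'   tips and valleys alternate all the way around, i.e. equal counts); use
#'   FALSE for leaflets whose margin is broken by the junction arc
#' @return list of per-tooth records (class `tooth_set`)
#' @export
tooth_geometry <- function(contour, tips, valleys, circular = NULL) {
  pts <- contour_points(contour)
  n <- nrow(pts)
  wrap <- if (is.null(circular)) length(tips) == length(valleys) && length(valleys) > 0
          else isTRUE(circular)
  teeth <- list()
  for (t in sort(tips)) {
    fl <- flank(t, sort(valleys), n, wrap)
    if (any(is.na(fl))) next
    vl <- fl[1]; vr <- fl[2]
    if (vl == vr) { warning("tooth with coincident flanking valleys skipped"); next }
    arc <- arc_indices(vl, vr, n)
    P <- pts[arc, , drop = FALSE]
    A <- pts[vl, ]; B <- pts[vr, ]; Tp <- pts[t, ]
    base_len <- sqrt(sum((B - A)^2))
    if (base_len < 1e-9) { warning("tooth with zero base skipped"); next }
    ang <- triangle_angles(Tp, A, B)
    teeth[[length(teeth) + 1]] <- list(
      tip_index = t, left_valley_index = vl, right_valley_index = vr,
      tip = Tp,
      height = dist_point_line(matrix(Tp, 1), A, B),
      area = abs(shoelace_area(P)),
      arc_length = polyline_length(P),
      base_length = base_len,
      perimeter = polyline_length(P) + base_len,
      tip_angle = ang[1], left_angle = ang[2], right_angle = ang[3])
  }
  if (length(teeth)) {
    arcs <- vapply(teeth, `[[`, numeric(1), "arc_length")
    total <- polyline_length(pts, closed = TRUE)
    ok <- arcs <= total / 4
    if (length(teeth) > 3) ok <- ok & arcs <= 10 * stats::median(arcs)
    if (!all(ok)) warning(sprintf("%d broken-margin tooth candidate(s) rejected", sum(!ok)))
    teeth <- teeth[ok]
  }
  structure(teeth, class = "tooth_set")
}

#' Per-valley (sinus) geometry
#'
#' Valleys are measured like teeth with the connection line drawn between
#' the two flanking tooth tips: valley depth is the perpendicular distance
#' from the sinus bottom to that line, valley area the area enclosed by the
#' margin arc and the line. Only sinuses flanked by teeth on both sides
#' (the distal serrated margin) are measured.
#'
#' @inheritParams tooth_geometry
#' @return list of per-valley records (class `valley_set`)
#' @export
valley_geometry <- function(contour, tips, valleys, circular = NULL) {
  pts <- contour_points(contour)
  n <- nrow(pts)
  wrap <- if (is.null(circular)) length(tips) == length(valleys) && length(tips) > 0
          else isTRUE(circular)
  out <- list()
  for (v in sort(valleys)) {
    fl <- flank(v, sort(tips), n, wrap)
    if (any(is.na(fl))) next
    tl <- fl[1]; tr <- fl[2]
    if (tl == tr) { warning("valley with coincident flanking tips skipped"); next }
    arc <- arc_indices(tl, tr, n)
    P <- pts[arc, , drop = FALSE]
    A <- pts[tl, ]; B <- pts[tr, ]
    out[[length(out) + 1]] <- list(
      bottom_index = v, left_tip_index = tl, right_tip_index = tr,
      bottom = pts[v, ],
      depth = dist_point_line(matrix(pts[v, ], 1), A, B),
      area = abs(shoelace_area(P)),
      arc_length = polyline_length(P),
      base_length = sqrt(sum((B - A)^2)))
  }
  structure(out, class = "valley_set")
}

#' Aggregate serration summary of a leaflet
#'
#' Combines tooth and valley measurements with the margin partition of the
#' blade: the valley-to-valley connection lines form the Tooth Base Line
#' (total length = Tooth Base Length); the line joining its start and end
#' points divides the blade into top and bottom parts; the top part is the
#' Outer Toothed Area; the area between the tooth base line and the dividing
#' line (teeth excluded) is the Inner Toothed Area; the total real tooth
#' border is the Length of Outer Edge; inner toothed area plus the bottom
#' part form the Inner Blade Area, bounded by the Blade Inner Perimeter.
#' Ratios: tooth_valley_area_ratio = total tooth / total valley area (NA
#' when no valleys), inner_toothed_area_ratio = inner toothed / blade area,
#' tooth_number_blade_ratio = tooth number / blade area, relative_tooth_area
#' = total tooth area / blade area. With zero teeth all counts and ratio
#' fields are 0 and tooth_valley_area_ratio is NA.
#'
#' @param record a `leaflet_record`
#' @param teeth a `tooth_set`
#' @param valleys a `valley_set`
#' @param blade a `blade_metrics`
#' @return object of class `serration_summary`
#' @export
serration_summary <- function(record, teeth, valleys, blade) {
  nT <- length(teeth); nV <- length(valleys)
  g <- function(set, f) vapply(set, `[[`, numeric(1), f)
  out <- list(tooth_number = nT, valley_number = nV)
  zero <- list(total_tooth_area = 0, mean_tooth_area = 0, total_tooth_height = 0,
               mean_tooth_height = 0, mean_tip_angle = NA_real_,
               mean_left_angle = NA_real_, mean_right_angle = NA_real_,
               tooth_base_length = 0, outer_toothed_area = 0,
               inner_toothed_area = 0, length_of_outer_edge = 0,
               inner_blade_area = blade$area,
               blade_inner_perimeter = blade$perimeter,
               total_valley_area = 0, mean_valley_area = 0, mean_valley_depth = 0,
               tooth_valley_area_ratio = NA_real_, inner_toothed_area_ratio = 0,
               tooth_number_blade_ratio = 0, relative_tooth_area = 0)
  if (nT == 0) return(structure(c(out, zero), class = "serration_summary"))

  pts <- contour_points(record$contour)
  n <- nrow(pts)
  areas <- g(teeth, "area"); heights <- g(teeth, "height")
  out$total_tooth_area <- sum(areas)
  out$mean_tooth_area <- mean(areas)
  out$total_tooth_height <- sum(heights)
  out$mean_tooth_height <- mean(heights)
  out$mean_tip_angle <- mean(g(teeth, "tip_angle"))
  out$mean_left_angle <- mean(g(teeth, "left_angle"))
  out$mean_right_angle <- mean(g(teeth, "right_angle"))
  out$tooth_base_length <- sum(g(teeth, "base_length"))
  out$length_of_outer_edge <- sum(g(teeth, "arc_length"))

  # dividing line: first tooth's left valley -> last tooth's right valley
  v0 <- teeth[[1]]$left_valley_index
  v1 <- teeth[[nT]]$right_valley_index
  arc <- arc_indices(v0, v1, n)
  outer_poly <- pts[arc, , drop = FALSE]
  out$outer_toothed_area <- abs(shoelace_area(outer_poly))
  out$inner_toothed_area <- max(0, out$outer_toothed_area - out$total_tooth_area)
  out$inner_blade_area <- blade$area - out$outer_toothed_area + out$inner_toothed_area
  toothed_arc_len <- polyline_length(outer_poly)
  out$blade_inner_perimeter <- out$tooth_base_length + (blade$perimeter - toothed_arc_len)

  if (nV > 0) {
    va <- g(valleys, "area")
    out$total_valley_area <- sum(va)
    out$mean_valley_area <- mean(va)
    out$mean_valley_depth <- mean(g(valleys, "depth"))
  } else {
    out$total_valley_area <- 0; out$mean_valley_area <- 0; out$mean_valley_depth <- 0
  }
  out$tooth_valley_area_ratio <-
    if (out$total_valley_area > 0) out$total_tooth_area / out$total_valley_area else NA_real_
  out$inner_toothed_area_ratio <- out$inner_toothed_area / blade$area
  out$tooth_number_blade_ratio <- nT / blade$area
  out$relative_tooth_area <- out$total_tooth_area / blade$area
  structure(out, class = "serration_summary")
}

#' @export
print.serration_summary <- function(x, ...) {
  cat(sprintf("<serration_summary> %d teeth, %d valleys; total tooth area %.0f px^2, base length %.1f px\n",
              x$tooth_number, x$valley_number, x$total_tooth_area, x$tooth_base_length))
  invisible(x)
}
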