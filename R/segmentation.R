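# Boundary tracing, centroid radial profiles, blade-stalk junction detection
# and separation of trifoliate leaves into terminal / lateral leaflet records.

#' Closed contour constructor
#'
#' @param points two-column matrix of (x, y) pixel coordinates, ordered along
#'   the boundary. Reoriented so the signed shoelace area is positive.
#' @param pixel_chain logical; TRUE when the points are an 8-connected pixel
#'   chain from [trace_contour()] (enables digitization-bias corrections).
#' @return object of class `leaf_contour`
#' @export
leaf_contour <- function(points, pixel_chain = FALSE) {
  points <- as.matrix(points)
  if (ncol(points) != 2 || nrow(points) < 3) stop("a contour needs >= 3 (x, y) points")
  colnames(points) <- c("x", "y")
  points <- ensure_positive_area(points)
  structure(points, class = "leaf_contour", pixel_chain = pixel_chain)
}

#' Extract the coordinate matrix of a contour
#' @param contour a `leaf_contour` or a plain two-column matrix
#' @export
contour_points <- function(contour) {
  m <- unclass(contour)
  attributes(m)[setdiff(names(attributes(m)), c("dim", "dimnames"))] <- NULL
  m
}

#' @export
print.leaf_contour <- function(x, ...) {
  cat(sprintf("<leaf_contour> %d points, area %.1f px^2%s\n",
              nrow(x), abs(shoelace_area(contour_points(x))),
              if (isTRUE(attr(x, "pixel_chain"))) ", pixel chain" else ""))
  invisible(x)
}

#' Trace the boundary of a single-component binary mask
#'
#' Moore-neighbour boundary following with Jacob's stopping criterion. The
#' returned chain is closed (last point adjacent to first) and oriented so
#' its signed area is positive.
#'
#' @param mask a `binary_mask` or logical matrix with exactly one connected
#'   component.
#' @return a `leaf_contour` of boundary pixel centres, as (x = col, y = row).
#' @export
trace_contour <- function(mask) {
  m <- mask_pixels(mask)
  if (!any(m)) stop("empty mask: nothing to trace")
  lab <- EBImage::bwlabel(m * 1L)
  if (max(lab) != 1) stop(sprintf("mask has %d connected components; expected exactly 1", max(lab)))
  H <- nrow(m); W <- ncol(m)
  pm <- matrix(FALSE, H + 2, W + 2)
  pm[2:(H + 1), 2:(W + 1)] <- m
  # start: topmost row, then leftmost column (in padded coordinates)
  rows <- which(apply(pm, 1, any))
  r0 <- rows[1]
  c0 <- which(pm[r0, ])[1]
  # clockwise Moore neighbourhood in (row, col), starting west
  nb <- matrix(c(0L, -1L, -1L, -1L, -1L, 0L, -1L, 1L, 0L, 1L, 1L, 1L, 1L, 0L, 1L, -1L),
               ncol = 2, byrow = TRUE)
  # entry came from the west (scan order guarantees west neighbour is bg)
  cur_r <- r0; cur_c <- c0
  back_dir <- 1L                       # index into nb pointing at the backtrack cell
  # offset -> neighbourhood index lookup for the backtrack computation
  dir_of <- matrix(0L, 3, 3)
  for (k in 1:8) dir_of[nb[k, 1] + 2L, nb[k, 2] + 2L] <- k
  max_steps <- 4L * sum(m) + 8L
  path <- matrix(0L, max_steps, 2)
  np <- 0L
  start_r <- r0; start_c <- c0
  start_back <- back_dir
  repeat {
    np <- np + 1L
    path[np, 1] <- cur_r; path[np, 2] <- cur_c
    found <- FALSE
    d <- back_dir
    for (k in 1:8) {
      d <- if (d == 8L) 1L else d + 1L
      rr <- cur_r + nb[d, 1]; cc <- cur_c + nb[d, 2]
      if (pm[rr, cc]) {
        # backtrack for the next step: the (background) neighbour checked
        # just before cand, re-indexed relative to the new current pixel
        prev <- if (d == 1L) 8L else d - 1L
        back_dir <- dir_of[nb[prev, 1] - nb[d, 1] + 2L, nb[prev, 2] - nb[d, 2] + 2L]
        cur_r <- rr; cur_c <- cc
        found <- TRUE
        break
      }
    }
    if (!found) break                  # isolated pixel
    if (cur_r == start_r && cur_c == start_c && back_dir == start_back) break
    if (np >= max_steps) stop("contour tracing failed to terminate")
  }
  pts <- cbind(x = path[seq_len(np), 2] - 1L, y = path[seq_len(np), 1] - 1L)
  # drop a duplicated closing point if present
  if (np > 1 && all(pts[np, ] == pts[1, ])) pts <- pts[-np, , drop = FALSE]
  if (nrow(pts) < 3) pts <- rbind(pts, pts[1, ], pts[1, ])  # degenerate 1-2 px blobs
  leaf_contour(pts, pixel_chain = TRUE)
}

#' Centroid radial profile of a contour
#'
#' Distances and angles from the area centroid to every contour point,
#' indexed along the contour. The centroid is the area centroid: the mean of
#' foreground pixels when a mask is supplied, otherwise the polygon centroid
#' of the contour (equivalent in the continuum).
#'
#' @param contour a `leaf_contour`
#' @param mask optional source `binary_mask` for a pixel-exact centroid
#' @return object of class `radial_profile`: list(centroid, distances,
#'   angles, contour)
#' @export
radial_profile <- function(contour, mask = NULL) {
  pts <- contour_points(contour)
  cen <- if (!is.null(mask)) {
    m <- mask_pixels(mask)
    idx <- which(m, arr.ind = TRUE)
    c(mean(idx[, 2]) - 1, mean(idx[, 1]) - 1)   # (x = col, y = row), 0-based
  } else polygon_centroid(pts)
  dx <- pts[, 1] - cen[1]
  dy <- pts[, 2] - cen[2]
  structure(list(centroid = cen,
                 distances = sqrt(dx^2 + dy^2),
                 angles = atan2(dy, dx),
                 contour = contour),
            class = "radial_profile")
}

#' @export
print.radial_profile <- function(x, ...) {
  cat(sprintf("<radial_profile> %d points, centroid (%.1f, %.1f), median distance %.1f px\n",
              length(x$distances), x$centroid[1], x$centroid[2], stats::median(x$distances)))
  invisible(x)
}

# All junction neck candidates of a profile: local radial minima below
# depth_fraction * median distance, corroborated by a sharp angle transition.
junction_candidates <- function(profile, depth_fraction = 0.5, window = 15,
                                smooth_window = 5, angle_min = 0.02) {
  d <- circ_ma(profile$distances, smooth_window)
  thr <- depth_fraction * stats::median(d)
  cp <- collapse_plateaus(d)
  ex <- extrema_5pt(cp$values, circular = TRUE)
  cand <- cp$index[ex$min]
  cand <- cand[d[cand] < thr]
  if (!length(cand)) return(integer(0))
  # angle corroboration: the unwrapped angle must swing quickly near a neck
  th <- profile$angles
  n <- length(th)
  swing <- vapply(cand, function(i) {
    w <- ((i - window):(i + window) - 1) %% n + 1
    a <- th[w]
    a <- atan2(sin(a - a[1]), cos(a - a[1]))   # unwrap relative to first
    diff(range(a))
  }, numeric(1))
  cand[swing >= angle_min]
}

# Pair each junction turning point with its partner across the stalk: the
# Euclidean-nearest contour point that is contour-far, connected by a chord
# that crosses tissue. The pair is refined to the tightest neck nearby.
pair_junction_candidates <- function(profile, cand, min_sep = 10, max_neck = Inf,
                                     window = 15) {
  pts <- contour_points(profile$contour)
  n <- nrow(pts)
  idx <- seq_len(n)
  partner_of <- function(a) {
    sep <- pmin(abs(idx - a), n - abs(idx - a))
    dd <- (pts[, 1] - pts[a, 1])^2 + (pts[, 2] - pts[a, 2])^2
    dd[sep < min_sep] <- Inf
    j <- which.min(dd)
    c(j, sqrt(dd[j]))
  }
  chord_ok <- function(a, b) {
    all(vapply(seq(0.25, 0.75, by = 0.25), function(t)
      point_in_polygon(pts, pts[a, ] + t * (pts[b, ] - pts[a, ])), logical(1)))
  }
  # process the deepest turning points first
  cand <- cand[order(profile$distances[cand])]
  pairs <- list()
  while (length(cand)) {
    a <- cand[1]
    cand <- cand[-1]
    pj <- partner_of(a)
    if (pj[2] > max_neck || !chord_ok(a, pj[1])) next
    # refine: slide the turning point locally and keep the tightest valid neck
    best <- c(a, pj[1], pj[2])
    for (a2 in unique(((a - 40):(a + 40) - 1) %% n + 1)) {
      pj2 <- partner_of(a2)
      if (pj2[2] < best[3]) best <- c(a2, pj2[1], pj2[2])
    }
    if (!chord_ok(best[1], best[2])) best <- c(a, pj[1], pj[2])
    pairs[[length(pairs) + 1]] <- sort(c(best[1], best[2]))
    # drop remaining turning points that belong to the same neck
    anchors <- best[1:2]
    cand <- cand[vapply(cand, function(i)
      all(pmin(abs(i - anchors), n - abs(i - anchors)) > window), logical(1))]
  }
  pairs
}

#' Locate the blade-stalk junction on a radial profile
#'
#' The junction is marked by two "turning points": local minima of the
#' centroid distance profile falling below `depth_fraction` times the median
#' distance, co-occurring with a sharp transition of the angle profile, and
#' lying closest together across the stalk. Serration sinus bottoms stay
#' above the depth threshold and are never selected.
#'
#' @param profile a [radial_profile()]
#' @param depth_fraction minima must fall below this fraction of the median
#'   centroid distance (default 0.5)
#' @param window index window for angle corroboration and candidate
#'   suppression (default 15 contour points)
#' @return integer vector of the two contour indices bounding the junction,
#'   with attribute `midpoint` (x, y of the junction midpoint)
#' @export
find_junction <- function(profile, depth_fraction = 0.5, window = 15) {
  cand <- junction_candidates(profile, depth_fraction, window)
  pairs <- pair_junction_candidates(profile, cand, window = window)
  if (!length(pairs)) stop("no junction found: no paired radial minima below the depth threshold")
  pts <- contour_points(profile$contour)
  gap <- vapply(pairs, function(p) sqrt(sum((pts[p[1], ] - pts[p[2], ])^2)), numeric(1))
  best <- pairs[[which.min(gap)]]
  structure(best, midpoint = colMeans(pts[best, , drop = FALSE]))
}

#' Cut a blade free of its stalk along the junction chord, on a contour
#'
#' Keeps the contour arc that does not traverse the stalk and closes it with
#' the straight junction segment.
#' @keywords internal
cut_blade_arc <- function(contour, junction) {
  pts <- contour_points(contour)
  n <- nrow(pts)
  i <- junction[1]; j <- junction[2]
  arc1 <- if (i <= j) i:j else c(i:n, 1:j)
  arc2 <- if (j <= i) j:i else c(j:n, 1:i)
  # the blade is the arc enclosing the larger area when closed by the chord;
  # the stalk arc encloses only the thin stalk
  score <- function(a) abs(shoelace_area(pts[a, , drop = FALSE]))
  blade_idx <- if (score(arc1) >= score(arc2)) arc1 else arc2
  leaf_contour(pts[blade_idx, , drop = FALSE],
               pixel_chain = isTRUE(attr(contour, "pixel_chain")))
}

#' One separated leaflet and its junction metadata
#'
#' @param contour blade `leaf_contour`
#' @param junction_endpoints 2 x 2 matrix of junction point coordinates
#' @param role one of "terminal", "left_lateral", "right_lateral"
#' @param meta named list of provenance fields (sample id, leaf index, ...)
#' @export
leaflet_record <- function(contour, junction_endpoints, role = NA_character_,
                           meta = list()) {
  je <- matrix(as.numeric(junction_endpoints), 2, 2)
  structure(list(contour = contour,
                 junction_endpoints = je,
                 junction_midpoint = colMeans(je),
                 role = role,
                 meta = meta),
            class = "leaflet_record")
}

#' @export
print.leaflet_record <- function(x, ...) {
  cat(sprintf("<leaflet_record> role=%s, %d contour points, junction midpoint (%.1f, %.1f)\n",
              x$role, nrow(x$contour), x$junction_midpoint[1], x$junction_midpoint[2]))
  invisible(x)
}

# stamp FALSE pixels along a segment (thick line) into a logical matrix;
# each end of the cut is extended along the chord direction until it leaves
# the foreground (the notch walls can seal against the stalk in raster
# space, so the junction chord alone does not always sever the neck)
erase_segment <- function(m, a, b, width = 3, max_overhang = 20) {
  L0 <- sqrt(sum((b - a)^2))
  u <- (b - a) / max(L0, 1e-9)
  probe_fg <- function(p) {
    r <- round(p[2]) + 1; c <- round(p[1]) + 1
    r >= 1 && r <= nrow(m) && c >= 1 && c <= ncol(m) && m[r, c]
  }
  ext_a <- 2
  while (ext_a < max_overhang && probe_fg(a - u * ext_a)) ext_a <- ext_a + 1
  ext_b <- 2
  while (ext_b < max_overhang && probe_fg(b + u * ext_b)) ext_b <- ext_b + 1
  a <- a - u * ext_a
  b <- b + u * ext_b
  L <- L0 + ext_a + ext_b
  ts <- seq(0, 1, length.out = max(2, ceiling(L * 2)))
  xs <- round(a[1] + ts * (b[1] - a[1]))
  ys <- round(a[2] + ts * (b[2] - a[2]))
  half <- (width - 1) / 2
  off <- expand.grid(dx = seq(-ceiling(half), ceiling(half)),
                     dy = seq(-ceiling(half), ceiling(half)))
  for (k in seq_len(nrow(off))) {
    r <- ys + off$dy[k] + 1
    c <- xs + off$dx[k] + 1
    ok <- r >= 1 & r <= nrow(m) & c >= 1 & c <= ncol(m)
    m[cbind(r[ok], c[ok])] <- FALSE
  }
  m
}

# width of a component: diameter of the largest inscribed circle
component_width <- function(m) {
  2 * max(EBImage::distmap(m * 1L))
}

# role labels for three blade centroids given the petiole base: terminal is
# farthest along the base->blades axis; in image coordinates (y down) the
# viewer-left lateral has positive cross product with that axis
assign_roles <- function(cents, base) {
  v <- colMeans(cents) - base
  v <- v / sqrt(sum(v^2))
  proj <- as.numeric((cents[, 1] - base[1]) * v[1] + (cents[, 2] - base[2]) * v[2])
  term <- which.max(proj)
  others <- setdiff(1:3, term)
  crossv <- (cents[others, 1] - base[1]) * v[2] - (cents[others, 2] - base[2]) * v[1]
  left <- others[which.max(crossv)]
  roles <- character(3)
  roles[term] <- "terminal"
  roles[left] <- "left_lateral"
  roles[setdiff(others, left)] <- "right_lateral"
  roles
}

# manual-junction separation: each sidecar pair is mapped to the nearest
# whole-leaf contour indices and the blade is the arc between them that
# contains no other junction pair
separate_leaflets_manual <- function(m0, junctions, meta = list()) {
  if (length(junctions) != 3)
    stop(sprintf("expected 3 manual junction pairs, found %d", length(junctions)))
  ct <- trace_contour(m0)
  pts <- contour_points(ct)
  n <- nrow(pts)
  nearest <- function(p) which.min((pts[, 1] - p[1])^2 + (pts[, 2] - p[2])^2)
  pairs <- lapply(junctions, function(p) {
    p <- matrix(as.numeric(p), 2, 2)
    sort(c(nearest(p[1, ]), nearest(p[2, ])))
  })
  blades <- lapply(seq_along(pairs), function(k) {
    i <- pairs[[k]][1]; j <- pairs[[k]][2]
    others <- unlist(pairs[-k])
    inside <- others > i & others < j
    idx <- if (any(inside)) c(j:n, 1:i) else i:j   # the arc free of other pairs
    leaf_contour(pts[idx, , drop = FALSE],
                 pixel_chain = isTRUE(attr(ct, "pixel_chain")))
  })
  cents <- t(vapply(blades, function(b) polygon_centroid(contour_points(b)), numeric(2)))
  # petiole base: the contour point farthest from the blade mass centre
  bc <- colMeans(cents)
  base <- pts[which.max((pts[, 1] - bc[1])^2 + (pts[, 2] - bc[2])^2), ]
  roles <- assign_roles(cents, base)
  records <- lapply(1:3, function(k)
    leaflet_record(blades[[k]], pts[pairs[[k]], , drop = FALSE],
                   role = roles[k], meta = meta))
  records[order(match(roles, c("terminal", "left_lateral", "right_lateral")))]
}

# Constriction (neck) detection on a closed boundary: for every contour
# point, the Euclidean-nearest contour-far point within max_neck; local
# minima of that width, with chords that cross tissue, are the necks where
# blades meet their stalks.
detect_necks <- function(pts, max_neck = 20, min_sep = 60, suppress = 12) {
  n <- nrow(pts)
  cell <- max_neck
  cx <- floor(pts[, 1] / cell); cy <- floor(pts[, 2] / cell)
  buckets <- split(seq_len(n), paste(cx, cy))
  w <- rep(Inf, n); partner <- integer(n)
  for (i in seq_len(n)) {
    neigh <- unlist(buckets[paste(rep(cx[i] + (-1:1), each = 3),
                                  rep(cy[i] + (-1:1), 3))], use.names = FALSE)
    if (!length(neigh)) next
    sep <- pmin(abs(neigh - i), n - abs(neigh - i))
    neigh <- neigh[sep >= min_sep]
    if (!length(neigh)) next
    dd <- (pts[neigh, 1] - pts[i, 1])^2 + (pts[neigh, 2] - pts[i, 2])^2
    k <- which.min(dd)
    if (dd[k] <= max_neck^2) { w[i] <- sqrt(dd[k]); partner[i] <- neigh[k] }
  }
  chord_ok <- function(a, b) {
    all(vapply(seq(0.2, 0.8, by = 0.15), function(t)
      point_in_polygon(pts, pts[a, ] + t * (pts[b, ] - pts[a, ])), logical(1)))
  }
  used <- rep(FALSE, n)
  necks <- list()
  for (i in order(w)) {
    if (!is.finite(w[i])) break
    j <- partner[i]
    if (used[i] || used[j]) next
    if (!chord_ok(i, j)) next
    necks[[length(necks) + 1]] <- sort(c(i, j))
    for (k in c(i, j)) used[((k - suppress):(k + suppress) - 1) %% n + 1] <- TRUE
  }
  necks
}

#' Separate a trifoliate leaf mask into terminal and lateral leaflet records
#'
#' Traces the whole-leaf boundary, finds blade-stalk junction necks from the
#' centroid radial profile (lateral leaflets on the first sweep, the terminal
#' leaflet from the rachis on a further sweep when needed), cuts the mask
#' along each junction chord, and classifies the resulting components into
#' blades and stalk. Roles are assigned geometrically: the terminal leaflet
#' lies farthest along the axis from the petiole base through the blades;
#' laterals are labelled left/right relative to that axis.
#'
#' @param leaf_mask `binary_mask` of one trifoliate leaf (blades plus
#'   petiole/rachis).
#' @param depth_fraction junction depth threshold, see [find_junction()]
#' @param min_blade_area minimum blade component area in px^2
#' @param min_blade_width minimum blade inscribed-circle diameter in px
#'   (separates blades from stalk fragments)
#' @param max_neck maximum junction chord length in px (real necks are at most about 1.5 stalk widths)
#' @param junctions optional manual override: list of 2 x 2 matrices of
#'   junction endpoint coordinates (sidecar corrections), used instead of
#'   detection.
#' @param meta named list stored on each record
#' @return list of three `leaflet_record`s ordered terminal, left_lateral,
#'   right_lateral.
#' @export
separate_leaflets <- function(leaf_mask, depth_fraction = 0.5,
                              min_blade_area = 2000, min_blade_width = 20,
                              max_neck = 20, junctions = NULL, meta = list()) {
  m0 <- mask_pixels(leaf_mask)
  if (!any(m0)) stop("empty leaf mask")
  # drop satellite specks (e.g. residual hair clusters) before tracing
  lab0 <- EBImage::bwlabel(m0 * 1L)
  sizes0 <- tabulate(lab0[lab0 > 0])
  big <- which(sizes0 >= min_blade_area)
  if (length(big) != 1)
    stop(sprintf("leaf mask has %d large components; expected one connected leaf",
                 length(big)))
  m0 <- matrix(lab0 == big, nrow(m0), ncol(m0))
  if (!is.null(junctions)) {
    # manual (sidecar) junctions: extract each blade arc directly on the
    # whole-leaf contour, which keeps blade areas exact
    return(separate_leaflets_manual(m0, junctions, meta))
  }
  ct <- trace_contour(m0)
  pts <- contour_points(ct)
  n <- nrow(pts)
  necks <- detect_necks(pts, max_neck = max_neck)
  ends <- unlist(necks)
  blades <- list(); junction_of <- list()
  for (nk in necks) {
    i <- nk[1]; j <- nk[2]
    others <- setdiff(ends, nk)
    in_arc1 <- others > i & others < j
    arc1 <- i:j
    arc2 <- c(j:n, 1:i)
    cand_arcs <- list()
    if (!any(in_arc1)) cand_arcs <- c(cand_arcs, list(arc1))
    if (!any(!in_arc1)) cand_arcs <- c(cand_arcs, list(arc2))
    for (arc in cand_arcs) {
      poly <- pts[arc, , drop = FALSE]
      area <- abs(shoelace_area(poly))
      if (area < min_blade_area) next
      # blade-shaped, not a stalk fragment: inscribed width via area/extent
      per <- polyline_length(poly, closed = TRUE)
      if (4 * pi * area / per^2 < 0.1) next
      blades[[length(blades) + 1]] <-
        leaf_contour(poly, pixel_chain = isTRUE(attr(ct, "pixel_chain")))
      junction_of[[length(blades)]] <- pts[nk, , drop = FALSE]
    }
  }
  if (length(blades) != 3)
    stop(sprintf("expected 3 separable blades, found %d", length(blades)))
  cents <- t(vapply(blades, function(b) polygon_centroid(contour_points(b)), numeric(2)))
  # petiole base: the contour point farthest from the blade mass centre
  bc <- colMeans(cents)
  base <- pts[which.max((pts[, 1] - bc[1])^2 + (pts[, 2] - bc[2])^2), ]
  roles <- assign_roles(cents, base)
  records <- lapply(1:3, function(b)
    leaflet_record(blades[[b]], junction_of[[b]], role = roles[b], meta = meta))
  out <- records[order(match(roles, c("terminal", "left_lateral", "right_lateral")))]
  attr(out, "junction_pairs") <- lapply(necks, function(nk) pts[nk, , drop = FALSE])
  out
}
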