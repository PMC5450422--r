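# Seeded generator of trifoliate leaf contours, rendered scan images and
# labelled populations with full ground truth. The generator stands in for
# scanned leaves in all tests: an elliptical blade with sawtooth serrations
# confined to the distal margin, a stalk (petiolule) emerging from a marked
# junction indentation at the proximal pole, smooth margin noise, and
# optional thin grayish trichome strokes at render time.

#' Parameter set for one synthetic leaflet
#'
#' @param base_a,base_b semi-axes (px) of the blade outline along the
#'   proximodistal and mediolateral axes
#' @param shape_exponent superellipse exponent of the base outline; 2 gives
#'   an ellipse, larger values a rounder-tipped, obovate-like blade
#' @param tooth_count number of serration teeth on the distal margin (>= 0)
#' @param tooth_height radial tooth amplitude (px)
#' @param toothed_arc fraction of the full margin carrying teeth, centred on
#'   the distal pole (default 0.6, the species' distal serration pattern)
#' @param tooth_skew asymmetry of the sawtooth rise/fall in (-1, 1); 0 gives
#'   symmetric triangular teeth
#' @param tooth_base_width tooth base arc width (px); caps how wide a tooth
#'   spreads when teeth are sparse
#' @param asymmetry blade skew factor; scales the radius by
#'   (1 + asymmetry * sin(phi)) so one flank is larger
#' @param margin_noise_sd standard deviation (px) of smooth margin noise
#' @param stalk_length,stalk_width stalk dimensions (px)
#' @param junction_depth radial depth of the blade-stalk junction
#'   indentation as a fraction of the smaller semi-axis (default 0.75)
#' @param notch_halfwidth angular half-width (radians) of the junction notch
#' @param n_points number of margin samples
#' @param seed RNG seed making the contour fully deterministic
#' @return object of class `leaflet_spec`
#' @export
leaflet_spec <- function(base_a = 110, base_b = 70, shape_exponent = 2,
                         tooth_count = 12,
                         tooth_height = 8, toothed_arc = 0.6, tooth_skew = 0.3,
                         tooth_base_width = 26,
                         asymmetry = 0, margin_noise_sd = 0.5,
                         stalk_length = 90, stalk_width = 8,
                         junction_depth = 0.75, notch_halfwidth = 0.18,
                         n_points = 2048, seed = 1) {
  sp <- list(base_a = base_a, base_b = base_b, shape_exponent = shape_exponent,
             tooth_count = round(tooth_count),
             tooth_height = tooth_height, toothed_arc = toothed_arc,
             tooth_skew = tooth_skew, tooth_base_width = tooth_base_width,
             asymmetry = asymmetry,
             margin_noise_sd = margin_noise_sd, stalk_length = stalk_length,
             stalk_width = stalk_width, junction_depth = junction_depth,
             notch_halfwidth = notch_halfwidth, n_points = n_points, seed = seed)
  stopifnot(base_a > 0, base_b > 0, sp$tooth_count >= 0,
            toothed_arc > 0, toothed_arc <= 1,
            stalk_length > 0, stalk_width > 0,
            junction_depth > 0, junction_depth < 1)
  if (tooth_height >= min(base_a, base_b))
    stop("inconsistent spec: tooth height must be smaller than the blade radius")
  structure(sp, class = "leaflet_spec")
}

# sample points along a straight segment at ~1.2 px spacing (endpoint excluded)
seg_points <- function(a, b, include_end = FALSE) {
  L <- sqrt(sum((b - a)^2))
  k <- max(2, ceiling(L / 1.2))
  ts <- seq(0, 1, length.out = k)
  if (!include_end) ts <- ts[-k]
  cbind(a[1] + ts * (b[1] - a[1]), a[2] + ts * (b[2] - a[2]))
}

#' Generate one synthetic leaflet contour with ground truth
#'
#' The margin is a polar outline r(phi) = base(phi) + teeth(phi) + noise,
#' with asymmetric sawtooth teeth confined to the distal toothed arc and a
#' junction indentation at the proximal pole from which the stalk emerges.
#' The blade is centred at the origin with the distal pole along +x.
#'
#' @param spec a [leaflet_spec()]
#' @return list(contour = `leaf_contour`, truth = list with tooth_count,
#'   tooth tip coordinates, junction endpoints/midpoint, blade polygon,
#'   blade area and blade length ground truth)
#' @export
make_leaflet_contour <- function(spec) {
  stopifnot(inherits(spec, "leaflet_spec"))
  a <- spec$base_a; b <- spec$base_b
  nu <- spec$notch_halfwidth
  n <- spec$n_points
  phi <- seq(-pi + nu, pi - nu, length.out = n)
  p <- spec$shape_exponent
  super_r <- function(ph) a * b / (abs(b * cos(ph))^p + abs(a * sin(ph))^p)^(1 / p)
  base_r <- super_r(phi) * (1 + spec$asymmetry * sin(phi))
  # sawtooth teeth over the distal window; the tooth base width is bounded
  # (real teeth keep a roughly constant base regardless of count), so sparse
  # teeth are sharp local bumps rather than cell-wide swells
  tooth <- numeric(n)
  tip_phi <- numeric(0)
  k <- spec$tooth_count
  if (k > 0) {
    A <- spec$toothed_arc * pi
    edges <- seq(-A, A, length.out = k + 1)
    w_cell <- diff(edges)[1]
    s <- 0.5 * (1 + spec$tooth_skew)
    centers <- edges[seq_len(k)] + w_cell / 2
    r_c <- super_r(centers)
    w_ang <- pmin(w_cell, spec$tooth_base_width / r_c)
    tip_phi <- centers - w_ang / 2 + s * w_ang
    for (kk in seq_len(k)) {
      lo <- centers[kk] - w_ang[kk] / 2
      inb <- phi >= lo & phi <= lo + w_ang[kk]
      u <- (phi[inb] - lo) / w_ang[kk]
      bump <- ifelse(u < s, u / s, (1 - u) / (1 - s))
      tooth[inb] <- tooth[inb] + spec$tooth_height * pmax(0, bump)
    }
  }
  noise <- if (spec$margin_noise_sd > 0) {
    with_seed(spec$seed, {
      z <- circ_ma(stats::rnorm(n), 21)
      z <- z / stats::sd(z) * spec$margin_noise_sd
      taper <- pmin(1, c(seq_len(30), rep(30, n - 60), rev(seq_len(30))) / 30)
      z * taper
    })
  } else numeric(n)
  r <- base_r + tooth + noise
  margin <- cbind(r * cos(phi), r * sin(phi))

  # junction notch walls and the stalk; the indentation depth is anchored to
  # the smaller semi-axis so the attachment radius scales with the median
  # centroid distance for elongated and round blades alike
  r_p <- super_r(pi)  # = a
  r_att <- (1 - spec$junction_depth) * min(a, b)
  half <- spec$stalk_width / 2
  if (r_att <= half * 1.2)
    stop("inconsistent spec: junction depth leaves no room for the stalk")
  x_att <- -sqrt(r_att^2 - half^2)
  corner_up <- c(x_att, half)
  corner_dn <- c(x_att, -half)
  x_tip <- -(r_p + spec$stalk_length)
  p_first <- margin[1, ]                 # phi = -pi + nu (lower side)
  p_last <- margin[n, ]                  # phi =  pi - nu (upper side)
  wall_up <- seg_points(p_last, corner_up)[-1, , drop = FALSE]
  # the stalk is narrowest at the blade joint and flares to full width over
  # the first few pixels (pulvinus), so the junction neck is geometrically
  # sharp and unique
  half_tip <- 1.35 * half
  x_flare <- x_att - min(15, spec$stalk_length / 2)
  stalk <- rbind(seg_points(corner_up, c(x_flare, half_tip)),
                 seg_points(c(x_flare, half_tip), c(x_tip, half_tip)),
                 seg_points(c(x_tip, half_tip), c(x_tip, -half_tip)),
                 seg_points(c(x_tip, -half_tip), c(x_flare, -half_tip)),
                 seg_points(c(x_flare, -half_tip), corner_dn))
  wall_dn <- seg_points(corner_dn, p_first)[-1, , drop = FALSE]
  pts <- rbind(margin, wall_up, stalk, wall_dn)
  contour <- leaf_contour(pts)

  # ground truth: blade polygon = margin + walls closed by the junction chord
  blade_poly <- rbind(margin, wall_up, corner_up, corner_dn,
                      wall_dn[-nrow(wall_dn), , drop = FALSE])
  jm <- c(x_att, 0)
  tips <- if (k > 0) {
    tr <- stats::approx(phi, r, xout = tip_phi)$y
    cbind(tr * cos(tip_phi), tr * sin(tip_phi))
  } else matrix(numeric(0), ncol = 2)
  cp <- contour_points(contour)
  nearest_idx <- function(p) which.min((cp[, 1] - p[1])^2 + (cp[, 2] - p[2])^2)
  truth <- list(tooth_count = k,
                tooth_tips = tips,
                junction_endpoints = rbind(corner_up, corner_dn),
                junction_midpoint = jm,
                junction_indices = c(nearest_idx(corner_up), nearest_idx(corner_dn)),
                blade_polygon = blade_poly,
                blade_area = abs(shoelace_area(blade_poly)),
                blade_length = max(sqrt((blade_poly[, 1] - jm[1])^2 +
                                        (blade_poly[, 2] - jm[2])^2)),
                spec = spec)
  list(contour = contour, truth = truth)
}

# --- rasterization helpers --------------------------------------------------

#' Scanline-fill a polygon into a logical pixel matrix
#' @param H,W canvas size in rows/columns
#' @param pts polygon vertices in 0-based (x = col, y = row) coordinates
#' @keywords internal
fill_polygon <- function(H, W, pts) {
  m <- matrix(FALSE, H, W)
  x <- pts[, 1]; y <- pts[, 2]
  n <- length(x)
  j <- c(2:n, 1)
  y0 <- max(0L, floor(min(y)))
  y1 <- min(H - 1L, ceiling(max(y)))
  for (row in y0:y1) {
    ya <- y; yb <- y[j]
    crosses <- (ya <= row & yb > row) | (yb <= row & ya > row)
    if (!any(crosses)) next
    xx <- x[crosses] + (row - ya[crosses]) * (x[j][crosses] - x[crosses]) /
      (yb[crosses] - ya[crosses])
    xx <- sort(xx)
    for (kk in seq(1, length(xx) - 1, by = 2)) {
      c0 <- max(0L, ceiling(xx[kk]))
      c1 <- min(W - 1L, floor(xx[kk + 1]))
      if (c1 >= c0) m[row + 1, (c0:c1) + 1] <- TRUE
    }
  }
  m
}

# stamp a thick line of given color into an RGB array (0-based coords)
draw_stroke <- function(px, a, b, width = 2, color = c(205, 205, 208)) {
  H <- dim(px)[1]; W <- dim(px)[2]
  L <- sqrt(sum((b - a)^2))
  ts <- seq(0, 1, length.out = max(2, ceiling(L * 2.5)))
  xs <- round(a[1] + ts * (b[1] - a[1]))
  ys <- round(a[2] + ts * (b[2] - a[2]))
  rng <- 0:(width - 1)
  for (dx in rng) for (dy in rng) {
    r <- ys + dy + 1; c <- xs + dx + 1
    ok <- r >= 1 & r <= H & c >= 1 & c <= W
    for (ch in 1:3) px[cbind(r[ok], c[ok], ch)] <- color[ch]
  }
  px
}

#' Render a trifoliate leaf scan image with ground truth
#'
#' Places three leaflets (left lateral, terminal, right lateral) with their
#' stalks meeting at the petiole/rachis node, terminal pointing up, petiole
#' extending down, green tissue on a dark or gray field, stamped at 800 dpi.
#' Optional thin grayish trichome strokes are drawn along blade margins.
#'
#' @param specs list of three [leaflet_spec()] (left, terminal, right), or a
#'   single spec reused for all three
#' @param trichome_density expected number of trichome strokes per leaflet
#' @param seed RNG seed for trichome placement
#' @param background `"dark"` or `"gray"` scanner field
#' @param lateral_angle angle (degrees) of the lateral leaflet axes from
#'   vertical
#' @param lateral_stalk_length,terminal_stalk_length stalk lengths (px) used
#'   for the rendered leaf (lateral leaflets are nearly sessile; the
#'   terminal sits on the rachis)
#' @param petiole_length,petiole_width petiole stroke geometry (px)
#' @param dpi resolution stamped on the image
#' @return list(image = `raster_image`, truth = ground-truth list with
#'   per-leaflet roles, blade masks and areas, junctions, tooth counts, and
#'   the hairless whole-leaf mask)
#' @export
render_leaf_image <- function(specs, trichome_density = 0, seed = 1,
                              background = c("dark", "gray"),
                              lateral_angle = 80, petiole_length = 240,
                              petiole_width = 7, lateral_stalk_length = 28,
                              terminal_stalk_length = 80, dpi = 800) {
  background <- match.arg(background)
  if (inherits(specs, "leaflet_spec")) {
    specs <- list(specs,
                  do.call(leaflet_spec, utils::modifyList(unclass(specs), list(seed = specs$seed + 1))),
                  do.call(leaflet_spec, utils::modifyList(unclass(specs), list(seed = specs$seed + 2))))
  }
  stopifnot(length(specs) == 3)
  # lateral leaflets are nearly sessile on the real plant; the rendered leaf
  # uses short lateral stalklets and a longer rachis for the terminal so the
  # blade-stalk junctions sit near the leaf centroid, as on real scans
  stalks <- c(lateral_stalk_length, terminal_stalk_length, lateral_stalk_length)
  # a wider junction sinus keeps the blade-stalk corners visible on the
  # traced raster boundary (a slit narrower than the stalk seals shut when
  # rasterized, hiding the true neck)
  specs <- lapply(1:3, function(i)
    do.call(leaflet_spec, utils::modifyList(unclass(specs[[i]]),
                                            list(stalk_length = stalks[i],
                                                 notch_halfwidth = 0.35))))
  roles <- c("left_lateral", "terminal", "right_lateral")
  la <- lateral_angle * pi / 180
  dirs <- list(c(-sin(la), -cos(la)), c(0, -1), c(sin(la), -cos(la)))

  gen <- lapply(specs, make_leaflet_contour)
  placed <- vector("list", 3)
  for (i in 1:3) {
    u <- dirs[[i]]
    ang <- atan2(u[2], u[1])
    R <- rot2(ang)
    sp <- specs[[i]]
    shift <- (sp$base_a + sp$stalk_length) * u
    tr <- function(p) sweep(p %*% t(R), 2, -shift)
    placed[[i]] <- list(
      contour = tr(contour_points(gen[[i]]$contour)),
      n_margin = specs[[i]]$n_points,
      blade_poly = tr(gen[[i]]$truth$blade_polygon),
      junction = tr(gen[[i]]$truth$junction_endpoints),
      tips = if (nrow(gen[[i]]$truth$tooth_tips)) tr(gen[[i]]$truth$tooth_tips)
             else gen[[i]]$truth$tooth_tips,
      centre = as.numeric(tr(matrix(0, 1, 2))),
      truth = gen[[i]]$truth)
  }
  all_pts <- do.call(rbind, lapply(placed, `[[`, "contour"))
  all_pts <- rbind(all_pts, c(0, petiole_length))
  margin <- 25
  off <- -c(min(all_pts[, 1]), min(all_pts[, 2])) + margin
  W <- ceiling(diff(range(all_pts[, 1])) + 2 * margin)
  H <- ceiling(diff(range(all_pts[, 2])) + 2 * margin)
  shift2 <- function(p) sweep(p, 2, -off)

  bgcol <- if (background == "dark") c(18, 18, 18) else c(128, 128, 128)
  px <- array(rep(bgcol, each = H * W), dim = c(H, W, 3))
  leaf_masks <- blade_masks <- vector("list", 3)
  for (i in 1:3) {
    placed[[i]]$contour <- shift2(placed[[i]]$contour)
    placed[[i]]$blade_poly <- shift2(placed[[i]]$blade_poly)
    placed[[i]]$junction <- shift2(placed[[i]]$junction)
    if (nrow(placed[[i]]$tips)) placed[[i]]$tips <- shift2(placed[[i]]$tips)
    placed[[i]]$centre <- placed[[i]]$centre + off
    leaf_masks[[i]] <- fill_polygon(H, W, placed[[i]]$contour)
    blade_masks[[i]] <- fill_polygon(H, W, placed[[i]]$blade_poly)
  }
  # stalks converge at the node by construction; only blade overlap is a
  # layout error (the acquisition protocol dissects overlapping leaflets)
  for (i in 1:2) for (j in (i + 1):3)
    if (any(blade_masks[[i]] & blade_masks[[j]]))
      stop("overlapping leaflets: adjust the layout or dissect the leaf")
  node <- off
  for (i in 1:3) {
    idx <- which(leaf_masks[[i]], arr.ind = TRUE)
    for (ch in 1:3) px[cbind(idx, ch)] <- c(50, 140, 55)[ch]
  }
  px <- draw_stroke(px, node - c(floor(petiole_width / 2), 0),
                    node - c(floor(petiole_width / 2), 0) + c(0, petiole_length),
                    width = petiole_width, color = c(55, 120, 50))
  hairless <- px
  if (trichome_density > 0) {
    px <- with_seed(seed, {
      out <- px
      for (i in 1:3) {
        bp <- placed[[i]]$blade_poly
        nt <- stats::rpois(1, trichome_density)
        if (nt > 0) {
          # trichomes develop on the leaflet margin, not on the stalks
          n_margin <- min(placed[[i]]$n_margin, nrow(bp))
          at <- sample(n_margin, min(nt, n_margin))
          for (p0 in at) {
            v <- bp[p0, ] - placed[[i]]$centre
            v <- v / max(1e-9, sqrt(sum(v^2)))
            jitter <- rot2(stats::runif(1, -0.35, 0.35))
            v <- as.numeric(jitter %*% v)
            len <- stats::runif(1, 5, 12)
            wdt <- sample(1:2, 1)
            out <- draw_stroke(out, bp[p0, ], bp[p0, ] + v * len,
                               width = wdt, color = c(205, 205, 208))
          }
        }
      }
      out
    })
  }
  img <- raster_image(px, dpi = dpi)
  truth <- list(
    roles = roles,
    blade_masks = blade_masks,
    blade_areas = vapply(blade_masks, sum, numeric(1)),
    leaf_masks = leaf_masks,
    junctions = lapply(placed, `[[`, "junction"),
    tooth_counts = vapply(gen, function(g) g$truth$tooth_count, numeric(1)),
    centres = lapply(placed, `[[`, "centre"),
    node = node,
    hairless_pixels = hairless,
    hairless_mask = !(hairless[, , 1] == bgcol[1] & hairless[, , 2] == bgcol[2] &
                        hairless[, , 3] == bgcol[3]))
  list(image = img, truth = truth)
}

#' Group layout for a synthetic leaflet population
#'
#' @param groups named list: each element a list of [leaflet_spec()] field
#'   means for one group (fields omitted fall back to spec defaults)
#' @param n_per_group samples per group
#' @param cv within-group coefficient of variation applied to size
#'   parameters (log-normal) and tooth counts (log-normal, rounded)
#' @param seed population seed
#' @export
population_spec <- function(groups, n_per_group = 32, cv = 0.09, seed = 1) {
  stopifnot(length(groups) >= 1, n_per_group >= 1)
  structure(list(groups = groups, n_per_group = n_per_group, cv = cv, seed = seed),
            class = "population_spec")
}

#' Generate a labelled leaflet population with ground truth
#'
#' Sizes are drawn log-normally around the group means (keeping positivity;
#' blade and margin measures of real leaves are right-skewed). The two
#' blade semi-axes share a common per-leaflet size factor with only a small
#' independent shape jitter (one third of the size coefficient of
#' variation): organ size varies far more between replicate leaves than
#' organ shape, so the length/width ratio is much less dispersed than
#' length itself. Tooth counts are rounded log-normal draws with the size
#' coefficient of variation. Fully deterministic given the population seed.
#'
#' @param pspec a [population_spec()] or preset name
#'   (`"heteroblasty6"`, `"mutants5"`, `"ecotypes4"`)
#' @param n_per_group,seed overrides applied to presets
#' @return list(contours, truths, labels, specs)
#' @export
make_population <- function(pspec, n_per_group = NULL, seed = NULL) {
  if (is.character(pspec)) pspec <- population_preset(pspec)
  stopifnot(inherits(pspec, "population_spec"))
  if (!is.null(n_per_group)) pspec$n_per_group <- n_per_group
  if (!is.null(seed)) pspec$seed <- seed
  labels <- character(0)
  specs <- list()
  with_seed(pspec$seed, {
    sl <- log(1 + pspec$cv^2)
    sl_shape <- log(1 + (pspec$cv / 3)^2)
    for (g in names(pspec$groups)) {
      gm <- pspec$groups[[g]]
      for (i in seq_len(pspec$n_per_group)) {
        draw <- function(m, s2 = sl) m * exp(stats::rnorm(1, -s2 / 2, sqrt(s2)))
        size_factor <- exp(stats::rnorm(1, -sl / 2, sqrt(sl)))
        fields <- list()
        for (f in names(gm)) {
          fields[[f]] <- if (f %in% c("base_a", "base_b"))
            gm[[f]] * size_factor * exp(stats::rnorm(1, -sl_shape / 2, sqrt(sl_shape)))
          else if (f %in% c("tooth_height", "stalk_length"))
            draw(gm[[f]])
          else if (f == "tooth_count") {
            if (gm[[f]] <= 0) 0 else max(0, round(draw(gm[[f]])))
          } else gm[[f]]
        }
        fields$seed <- sample.int(2^30, 1)
        specs[[length(specs) + 1]] <- do.call(leaflet_spec, fields)
        labels <- c(labels, g)
      }
    }
  })
  gen <- lapply(specs, make_leaflet_contour)
  list(contours = lapply(gen, `[[`, "contour"),
       truths = lapply(gen, `[[`, "truth"),
       labels = labels,
       specs = specs)
}

#' Built-in population presets
#'
#' `heteroblasty6` mimics the developmental series L1..L6 (n = 32 per node
#' group): tooth number falling almost linearly from 40 to 10, blade size
#' peaking at L2-L3, and the length/width ratio declining below 1 only in
#' L6. `mutants5` mimics a wild type plus five developmental mutants with
#' strongly distinct blades (including a toothless smooth-margin mutant and
#' a small, nearly circular one). `ecotypes4` mimics four natural variants
#' with moderate differences.
#'
#' @param name preset name
#' @return a [population_spec()]
#' @export
population_preset <- function(name = c("heteroblasty6", "mutants5", "ecotypes4")) {
  name <- match.arg(name)
  g <- switch(name,
    heteroblasty6 = {
      tooth <- c(40, 34, 28, 22, 16, 10)
      a <- c(80, 115, 112, 100, 88, 78)
      ratio <- c(2.1, 1.9, 1.65, 1.45, 1.2, 0.95)
      th <- c(6, 7, 7.5, 8, 8.5, 9)
      gl <- lapply(1:6, function(i) list(base_a = a[i], base_b = a[i] / ratio[i],
                                         tooth_count = tooth[i], tooth_height = th[i]))
      names(gl) <- paste0("L", 1:6)
      population_spec(gl, n_per_group = 32, cv = 0.09, seed = 1)
    },
    mutants5 = {
      gl <- list(
        WT = list(base_a = 110, base_b = 68, tooth_count = 20, tooth_height = 8),
        m1 = list(base_a = 85, base_b = 60, tooth_count = 0, tooth_height = 8),
        m2 = list(base_a = 55, base_b = 50, tooth_count = 9, tooth_height = 5),
        m3 = list(base_a = 105, base_b = 58, tooth_count = 6, tooth_height = 7),
        m4 = list(base_a = 95, base_b = 52, tooth_count = 14, tooth_height = 7),
        m5 = list(base_a = 145, base_b = 70, tooth_count = 34, tooth_height = 9))
      population_spec(gl, n_per_group = 20, cv = 0.08, seed = 1)
    },
    ecotypes4 = {
      gl <- list(
        A17      = list(base_a = 100, base_b = 62, tooth_count = 22, tooth_height = 9),
        PI516927 = list(base_a = 125, base_b = 80, tooth_count = 30, tooth_height = 8),
        PI516939 = list(base_a = 100, base_b = 60, tooth_count = 21, tooth_height = 6),
        PI577609 = list(base_a = 115, base_b = 82, tooth_count = 26, tooth_height = 7))
      population_spec(gl, n_per_group = 20, cv = 0.09, seed = 1)
    })
  g
}

#' Check that a closed polygon is simple (no self-intersections)
#'
#' Grid-bucketed segment intersection scan; non-adjacent edge pairs only.
#' @param pts polygon vertex matrix
#' @return TRUE when no crossing is found
#' @export
is_simple_polygon <- function(pts) {
  n <- nrow(pts)
  j <- c(2:n, 1)
  x1 <- pts[, 1]; y1 <- pts[, 2]; x2 <- pts[j, 1]; y2 <- pts[j, 2]
  cell <- 16
  cx <- floor(pmin(x1, x2) / cell); cy <- floor(pmin(y1, y2) / cell)
  # segments are short; bucket by lower-left cell and compare within the
  # 3x3 cell neighbourhood
  key <- paste(cx, cy)
  buckets <- split(seq_len(n), key)
  seg_int <- function(i, k) {
    d1 <- c(x2[i] - x1[i], y2[i] - y1[i])
    d2 <- c(x2[k] - x1[k], y2[k] - y1[k])
    den <- d1[1] * d2[2] - d1[2] * d2[1]
    if (abs(den) < 1e-12) return(FALSE)
    w <- c(x1[k] - x1[i], y1[k] - y1[i])
    t <- (w[1] * d2[2] - w[2] * d2[1]) / den
    s <- (w[1] * d1[2] - w[2] * d1[1]) / den
    t > 1e-9 && t < 1 - 1e-9 && s > 1e-9 && s < 1 - 1e-9
  }
  for (bk in names(buckets)) {
    xy <- as.numeric(strsplit(bk, " ")[[1]])
    near <- unlist(buckets[paste(rep(xy[1] + -1:1, each = 3), rep(xy[2] + -1:1, 3))],
                   use.names = FALSE)
    near <- near[!is.na(near)]
    for (i in buckets[[bk]]) for (k in near) {
      if (k <= i) next
      gap <- min(abs(i - k), n - abs(i - k))
      if (gap <= 1) next
      if (seg_int(i, k)) return(FALSE)
    }
  }
  TRUE
}
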