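# Shared fixtures, all generated in code. Heavier fixtures are built once
# per session and memoised in this environment.

.fx <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fx[[key]])) .fx[[key]] <- force(expr)
  .fx[[key]]
}

# dense polygon of a circle / ellipse
ellipse_contour <- function(a, b = a, n = 4000, centre = c(0, 0)) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  leaf_contour(cbind(centre[1] + a * cos(th), centre[2] + b * sin(th)))
}

# filled digital disk mask
disk_mask <- function(r, pad = 20) {
  sz <- 2 * (r + pad)
  cc <- r + pad
  m <- outer(seq_len(sz), seq_len(sz), function(i, j) (i - cc)^2 + (j - cc)^2 <= r^2)
  m
}

# dense-edged square polygon (side s, lower-left at origin)
square_contour <- function(s = 100) {
  v <- rbind(c(0, 0), c(s, 0), c(s, s), c(0, s))
  leaf_contour(do.call(rbind, lapply(1:4, function(i) {
    a <- v[i, ]; b <- v[if (i == 4) 1 else i + 1, ]
    k <- 200
    ts <- seq(0, 1, length.out = k + 1)[-(k + 1)]
    cbind(a[1] + ts * (b[1] - a[1]), a[2] + ts * (b[2] - a[2]))
  })))
}

# leaflet whose tooth count and blade elongation co-vary as on successive
# nodes (many-toothed young leaves are elongated, few-toothed old ones round)
recovery_spec <- function(tooth_count, seed) {
  ratio <- 0.95 + (2.1 - 0.95) * (tooth_count - 5) / 35
  leaflet_spec(base_a = 100, base_b = 100 / ratio, tooth_count = tooth_count,
               seed = seed)
}

# separate a generator leaflet contour into blade + junction metadata
blade_of <- function(gen) {
  prof <- radial_profile(gen$contour)
  j <- find_junction(prof)
  pts <- contour_points(gen$contour)
  list(record = leaflet_record(leafletkit:::cut_blade_arc(gen$contour, j),
                               pts[j, , drop = FALSE]),
       junction = pts[j, , drop = FALSE],
       indices = j)
}

# count teeth on a contour, excluding the junction arc given its endpoints
count_teeth <- function(contour, junction_endpoints = NULL) {
  exclude <- if (!is.null(junction_endpoints))
    junction_arc_indices(contour, junction_endpoints) else NULL
  ex <- detect_extrema(radial_profile(contour), exclude = exclude)
  length(suppressWarnings(
    tooth_geometry(contour, ex$tips, ex$valleys,
                   circular = if (is.null(exclude)) NULL else FALSE)))
}

# standard trifoliate render (memoised: used by several test files)
trifoliate_fixture <- function(trichomes = 0, seed = 1) {
  memo(sprintf("tri_%d_%d", trichomes, seed),
       render_leaf_image(list(leaflet_spec(tooth_count = 11, seed = 1),
                              leaflet_spec(tooth_count = 15, base_a = 125, seed = 11),
                              leaflet_spec(tooth_count = 11, seed = 21)),
                         trichome_density = trichomes, seed = seed))
}

# measured feature tables of the built-in presets (memoised; also used by
# the acceptance suite)
preset_features <- function(name) {
  memo(paste0("feats_", name), {
    pop <- make_population(name)
    suppressWarnings(population_features(pop))
  })
}

expect_rel_equal <- function(x, y, tol) {
  expect_lt(abs(x - y) / max(abs(y), 1e-12), tol)
}
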