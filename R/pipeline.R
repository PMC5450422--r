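# Batch orchestration: scan directory -> per-leaflet feature table ->
# statistics / classification reports, with config, sidecar corrections,
# per-image error isolation and deterministic CSV export.

# parameters reported in px and their mm / mm^2 conversions
.len_params <- c("blade_length", "blade_width", "blade_perimeter",
                 "total_tooth_height", "mean_tooth_height", "tooth_base_length",
                 "length_of_outer_edge", "blade_inner_perimeter",
                 "mean_valley_depth", "total_tooth_perimeter", "mean_tooth_perimeter")
.area_params <- c("blade_area", "total_tooth_area", "mean_tooth_area",
                  "outer_toothed_area", "inner_toothed_area", "inner_blade_area",
                  "total_valley_area", "mean_valley_area")

#' Measure all blade, serration and spectral parameters of one leaflet
#'
#' Runs the full measurement stack on a separated leaflet: blade length /
#' width / shape parameters, tooth and valley detection and geometry along
#' the margin (the junction arc is excluded from the extremum search), the
#' margin partition summary, and the elliptic Fourier band powers.
#'
#' @param record a `leaflet_record`
#' @param min_prominence serration prominence threshold, see
#'   [detect_extrema()]
#' @param n_harmonics,band_edges EFD settings
#' @param power_mode half-power accumulation mode, see [band_summary()]
#' @param include_harmonics add A_001..A_nnn amplitude columns
#' @param midvein_points optional manual midvein control points (curved
#'   blade length mode)
#' @return one-row data.frame of named parameters in px units
#' @export
measure_leaflet <- function(record, min_prominence = NULL, n_harmonics = 120,
                            band_edges = c(19, 55, 120),
                            power_mode = c("amplitude", "power"),
                            include_harmonics = FALSE, midvein_points = NULL) {
  power_mode <- match.arg(power_mode)
  pts <- contour_points(record$contour)
  n <- nrow(pts)
  L <- if (!is.null(midvein_points))
    blade_length_curved(record, midvein_points)$L else blade_length(record)$L
  W <- blade_width(record)$W
  blade <- blade_shape_params(record, L = L, W = W)
  # exclude the junction arc (cut chord plus the sector it subtends) from
  # the extremum search so the blade base is never scored as tooth or sinus;
  # rotate the contour to start just after that arc so that array order is
  # margin order and tooth/valley flanking never straddles the gap
  near <- junction_arc_indices(record$contour, record$junction_endpoints)
  work <- record$contour
  if (length(near) && length(near) < n) {
    in_gap <- seq_len(n) %in% near
    # end of the largest circular excluded run
    shifted <- c(in_gap[-1], in_gap[1])
    run_ends <- which(in_gap & !shifted)
    if (!length(run_ends)) run_ends <- max(near)
    runlen <- vapply(run_ends, function(e) {
      l <- 0L; i <- e
      while (in_gap[i] && l < n) { l <- l + 1L; i <- if (i == 1L) n else i - 1L }
      l
    }, integer(1))
    i0 <- run_ends[which.max(runlen)] %% n + 1L
    perm <- c(i0:n, if (i0 > 1) 1:(i0 - 1))
    inv <- integer(n); inv[perm] <- seq_len(n)
    work <- leaf_contour(pts[perm, , drop = FALSE],
                         pixel_chain = isTRUE(attr(record$contour, "pixel_chain")))
    near <- sort(inv[near])
  }
  prof <- radial_profile(work)
  ext <- detect_extrema(prof, min_prominence = min_prominence, exclude = near)
  teeth <- tooth_geometry(work, ext$tips, ext$valleys, circular = FALSE)
  valleys <- valley_geometry(work, ext$tips, ext$valleys, circular = FALSE)
  ser_record <- record; ser_record$contour <- work
  ser <- serration_summary(ser_record, teeth, valleys, blade)
  sp <- efd_transform(record$contour, n_harmonics = n_harmonics,
                      band_edges = band_edges)
  bs <- band_summary(sp, mode = power_mode)
  tperi <- vapply(teeth, `[[`, numeric(1), "perimeter")
  row <- c(list(blade_length = blade$length, blade_width = blade$width,
                blade_area = blade$area, blade_perimeter = blade$perimeter,
                length_width_ratio = blade$length_width_ratio,
                leaflet_symmetry = blade$symmetry,
                compactness = blade$compactness),
           unclass(ser)[c("tooth_number", "total_tooth_area", "mean_tooth_area",
                          "total_tooth_height", "mean_tooth_height",
                          "mean_tip_angle", "mean_left_angle", "mean_right_angle",
                          "tooth_base_length", "outer_toothed_area",
                          "inner_toothed_area", "length_of_outer_edge",
                          "inner_blade_area", "blade_inner_perimeter",
                          "valley_number", "total_valley_area", "mean_valley_area",
                          "mean_valley_depth", "tooth_valley_area_ratio",
                          "inner_toothed_area_ratio", "tooth_number_blade_ratio",
                          "relative_tooth_area")],
           list(total_tooth_perimeter = if (length(tperi)) sum(tperi) else 0,
                mean_tooth_perimeter = if (length(tperi)) mean(tperi) else 0,
                delta_power = bs$delta_power, alpha_power = bs$alpha_power,
                beta_power = bs$beta_power,
                half_power_frequency = bs$half_power_frequency))
  out <- as.data.frame(row)
  if (include_harmonics) {
    amp <- as.list(sp$amplitude)
    names(amp) <- sprintf("A_%03d", seq_along(amp))
    out <- cbind(out, as.data.frame(amp))
  }
  out
}

#' Measure a free-standing leaflet contour (blade plus stalk)
#'
#' Finds the blade-stalk junction on the radial profile, cuts the blade arc
#' free, and measures it with [measure_leaflet()].
#'
#' @param contour a `leaf_contour` of a leaflet with its stalk
#' @param depth_fraction junction depth threshold
#' @param ... forwarded to [measure_leaflet()]
#' @return one-row data.frame
#' @export
measure_leaflet_contour <- function(contour, depth_fraction = 0.5, ...) {
  prof <- radial_profile(contour)
  j <- find_junction(prof, depth_fraction = depth_fraction)
  pts <- contour_points(contour)
  blade <- cut_blade_arc(contour, j)
  rec <- leaflet_record(blade, pts[j, , drop = FALSE])
  measure_leaflet(rec, ...)
}

# tiny polynomial hash for provenance stamps (no external digest dependency)
fnv1a <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = ""))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2^31
  sprintf("%08x", h)
}

#' Default run configuration
#'
#' @param input_paths image files or directories to process
#' @param output_dir where the feature CSV and reports are written (NULL:
#'   nothing written)
#' @param background scanner background model
#' @param dpi_default dpi assumed for files without metadata
#' @param remove_trichomes apply YCbCr trichome removal
#' @param exclude_first_leaf drop the first (juvenile) leaf of every scan
#' @param min_prominence serration threshold (NULL: adaptive default)
#' @param n_harmonics,band_edges,power_mode EFD settings
#' @param units `"px"` or `"mm"` (mm adds converted columns)
#' @param include_harmonics export A_001.. amplitude columns
#' @param seed master seed recorded in outputs
#' @return list of class `run_config`
#' @export
run_config <- function(input_paths = character(0), output_dir = NULL,
                       background = "dark", dpi_default = 800,
                       remove_trichomes = TRUE, exclude_first_leaf = FALSE,
                       min_prominence = NULL, n_harmonics = 120,
                       band_edges = c(19, 55, 120), power_mode = "amplitude",
                       units = "px", include_harmonics = FALSE, seed = 1) {
  structure(list(input_paths = input_paths, output_dir = output_dir,
                 background = background, dpi_default = dpi_default,
                 remove_trichomes = remove_trichomes,
                 exclude_first_leaf = exclude_first_leaf,
                 min_prominence = min_prominence, n_harmonics = n_harmonics,
                 band_edges = band_edges, power_mode = power_mode,
                 units = units, include_harmonics = include_harmonics,
                 seed = seed),
            class = "run_config")
}

#' Read a run configuration from YAML or JSON
#' @param path config file
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("unreadable config: ", path)
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
         else jsonlite::fromJSON(path, simplifyVector = TRUE)
  do.call(run_config, raw[intersect(names(raw), names(formals(run_config)))])
}

# read a sidecar correction file for an image, if present
read_sidecar <- function(image_path) {
  sc <- paste0(tools::file_path_sans_ext(image_path), ".sidecar.json")
  if (!file.exists(sc)) return(NULL)
  jsonlite::fromJSON(sc, simplifyVector = FALSE)
}

#' Run the batch pipeline over scan images
#'
#' For every image: segment, optionally remove trichomes, split the scan
#' into ordered leaves, separate each trifoliate leaf into three leaflet
#' records (sidecar corrections applied when present), and measure every
#' leaflet. Failures are logged with image and leaf index and skipped;
#' a failing leaf never aborts the batch.
#'
#' @param config a [run_config()], or path to a YAML/JSON config
#' @return data.frame feature table (metadata + parameters); failures in
#'   attribute `"failures"`. Written to `output_dir/features.csv` when an
#'   output directory is configured.
#' @export
run_batch <- function(config) {
  if (is.character(config)) config <- read_config(config)
  stopifnot(inherits(config, "run_config"))
  paths <- unlist(lapply(config$input_paths, function(p) {
    if (dir.exists(p)) list.files(p, pattern = "\\.(tif|tiff|png)$",
                                  ignore.case = TRUE, full.names = TRUE) else p
  }))
  paths <- sort(paths)
  rows <- list()
  failures <- character(0)
  add_failure <- function(msg) failures[length(failures) + 1] <<- msg
  add_row <- function(r) rows[[length(rows) + 1]] <<- r
  process_leaf <- function(leaf_mask, path, li, sidecar) {
    junctions <- NULL
    midveins <- list()
    if (!is.null(sidecar)) {
      for (corr in sidecar$corrections) {
        if (!is.null(corr$leaf_index) && corr$leaf_index != li) next
        if (!is.null(corr$junction_px))
          junctions <- c(junctions, list(do.call(rbind, lapply(corr$junction_px, unlist))))
        if (!is.null(corr$midvein_px) && !is.null(corr$leaflet_role))
          midveins[[corr$leaflet_role]] <- do.call(rbind, lapply(corr$midvein_px, unlist))
      }
    }
    recs <- separate_leaflets(leaf_mask, junctions = junctions,
                              meta = list(image = basename(path), leaf_index = li))
    for (rec in recs) {
      row <- measure_leaflet(rec, min_prominence = config$min_prominence,
                             n_harmonics = config$n_harmonics,
                             band_edges = config$band_edges,
                             power_mode = config$power_mode,
                             include_harmonics = config$include_harmonics,
                             midvein_points = midveins[[rec$role]])
      meta <- data.frame(image = basename(path), leaf_index = li,
                         leaflet_role = rec$role,
                         dpi = obj_dpi(leaf_mask, config$dpi_default))
      add_row(cbind(meta, row))
    }
  }
  for (path in paths) {
    tryCatch({
      img <- load_scan(path, dpi_override = config$dpi_default)
      mask <- segment_foreground(img, background = config$background)
      if (config$remove_trichomes) mask <- remove_trichomes(img, mask)
      leaves <- split_leaves(mask)
      if (config$exclude_first_leaf && length(leaves)) leaves <- leaves[-1]
      sidecar <- read_sidecar(path)
      for (li in seq_along(leaves)) {
        tryCatch(process_leaf(leaves[[li]], path, li, sidecar),
                 error = function(e) add_failure(
                   sprintf("%s leaf %d: %s", basename(path), li, conditionMessage(e))))
      }
    }, error = function(e) add_failure(
      sprintf("%s: %s", basename(path), conditionMessage(e))))
  }
  tab <- if (length(rows)) do.call(rbind, rows) else data.frame()
  attr(tab, "failures") <- failures
  # hash only the analysis-relevant settings, not filesystem locations
  attr(tab, "config_hash") <- fnv1a(unclass(config)[setdiff(names(config),
                                    c("input_paths", "output_dir"))])
  attr(tab, "seed") <- config$seed
  if (!is.null(config$output_dir) && nrow(tab)) {
    dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
    export_features(tab, file.path(config$output_dir, "features.csv"),
                    units = config$units)
  }
  for (f in failures) message("pipeline: skipped ", f)
  tab
}

#' Export a feature table as CSV
#'
#' Stable column order (metadata, blade, serration, spectral); with
#' `units = "mm"` every length column gains a `_mm` twin and every area
#' column a `_mm2` twin using mm = px * 25.4 / dpi. A provenance header
#' comment embeds the package version and config hash.
#'
#' @param table feature data.frame (from [run_batch()] or assembled)
#' @param path output CSV path
#' @param units `"px"` or `"mm"`
#' @param dpi conversion resolution used when the table has no dpi column
#' @return the path, invisibly
#' @export
export_features <- function(table, path, units = c("px", "mm"), dpi = 800) {
  units <- match.arg(units)
  if (!nrow(table)) stop("empty feature table")
  tab <- table
  if (units == "mm") {
    k <- 25.4 / (if (!is.null(tab$dpi)) tab$dpi else dpi)
    for (p in intersect(.len_params, names(tab))) tab[[paste0(p, "_mm")]] <- tab[[p]] * k
    for (p in intersect(.area_params, names(tab))) tab[[paste0(p, "_mm2")]] <- tab[[p]] * k^2
  }
  con <- file(path, open = "wt")
  on.exit(close(con))
  hash <- attr(table, "config_hash")
  writeLines(sprintf("# leafletkit %s config_hash %s",
                     as.character(utils::packageVersion("leafletkit")),
                     if (is.null(hash)) fnv1a(names(tab)) else hash), con)
  utils::write.csv(tab, con, row.names = FALSE)
  invisible(path)
}

#' Measure every contour of a synthetic population
#'
#' Convenience wrapper running [measure_leaflet_contour()] on each generated
#' leaflet and binding the rows with their group labels.
#'
#' @param pop result of [make_population()]
#' @param ... forwarded to [measure_leaflet_contour()]
#' @return data.frame with a `group` column plus all parameters
#' @export
population_features <- function(pop, ...) {
  rows <- lapply(seq_along(pop$contours), function(i) {
    r <- measure_leaflet_contour(pop$contours[[i]], ...)
    cbind(data.frame(group = pop$labels[i]), r)
  })
  do.call(rbind, rows)
}
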