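# Elliptic Fourier description of leaflet contours: classical four-coefficient
# harmonics, invariance normalization (rotation, translation, starting point;
# size deliberately preserved), combined amplitude spectrum, Delta/Alpha/Beta
# band powers, half-power frequency, and band-limited reconstruction.

#' Elliptic Fourier transform of a closed contour
#'
#' Computes the classical elliptic Fourier coefficients (a_n, b_n for x;
#' c_n, d_n for y) of a closed contour after resampling it to `n_points`
#' equally spaced arc-length positions. The normalized coefficients are
#' invariant to translation (the constant term is dropped), rotation and
#' starting point (first-harmonic phase normalization) but NOT to scale:
#' the description reflects both the shape and the size of the blade.
#' Per-axis amplitudes are A(f)x = sqrt(a_f^2 + b_f^2), A(f)y =
#' sqrt(c_f^2 + d_f^2), combined as A(f)^2 = A(f)x^2 + A(f)y^2.
#'
#' @param contour a `leaf_contour` (or 2-column matrix) with at least 3
#'   distinct points
#' @param n_harmonics number of harmonics (default 120)
#' @param n_points arc-length resampling resolution before the transform
#'   (raised automatically when `n_harmonics` demands it)
#' @param band_edges upper harmonic of the Delta, Alpha and Beta bands
#' @return object of class `efd_spectrum` with raw and normalized
#'   coefficients, per-axis and combined amplitudes, and the normalization
#'   angles (stored so reconstruction returns to image coordinates)
#' @export
efd_transform <- function(contour, n_harmonics = 120, n_points = 2048,
                          band_edges = c(19, 55, 120)) {
  pts <- contour_points(if (inherits(contour, "leaf_contour")) contour
                        else leaf_contour(as.matrix(contour)))
  if (n_harmonics < 1) stop("n_harmonics must be >= 1")
  # the piecewise-linear coefficient integrals are exact on the polygon, so
  # a contour with enough vertices is transformed directly (keeping rotation
  # and starting-point invariance exact); short contours are upsampled to
  # satisfy the harmonic sampling requirement
  np <- max(n_points, 2 * n_harmonics + 8)
  rs <- if (nrow(pts) >= np) pts else resample_closed(pts, np)
  np <- nrow(rs)
  d <- rbind(diff(rs), rs[1, ] - rs[np, ])
  dt <- sqrt(rowSums(d^2))
  keep <- dt > 1e-12
  d <- d[keep, , drop = FALSE]; dt <- dt[keep]
  tcum <- cumsum(dt)
  Tt <- tcum[length(tcum)]
  t0 <- c(0, tcum[-length(tcum)])
  n <- seq_len(n_harmonics)
  phi1 <- outer(n, 2 * pi * tcum / Tt)       # N x K
  phi0 <- outer(n, 2 * pi * t0 / Tt)
  const <- Tt / (2 * pi^2 * n^2)
  vx <- d[, 1] / dt
  vy <- d[, 2] / dt
  dcos <- cos(phi1) - cos(phi0)
  dsin <- sin(phi1) - sin(phi0)
  a <- const * as.numeric(dcos %*% vx)
  b <- const * as.numeric(dsin %*% vx)
  cc <- const * as.numeric(dcos %*% vy)
  dd <- const * as.numeric(dsin %*% vy)
  # constant (dc) terms
  xi <- cumsum(d[, 1]) - vx * tcum
  delta <- cumsum(d[, 2]) - vy * tcum
  A0 <- rs[1, 1] + sum(vx / 2 * (tcum^2 - t0^2) + xi * (tcum - t0)) / Tt
  C0 <- rs[1, 2] + sum(vy / 2 * (tcum^2 - t0^2) + delta * (tcum - t0)) / Tt
  # starting-point phase from the first harmonic
  theta <- 0.5 * atan2(2 * (a[1] * b[1] + cc[1] * dd[1]),
                       a[1]^2 + cc[1]^2 - b[1]^2 - dd[1]^2)
  ctn <- cos(n * theta); stn <- sin(n * theta)
  a1 <- a * ctn + b * stn;  b1 <- -a * stn + b * ctn
  c1 <- cc * ctn + dd * stn; d1 <- -cc * stn + dd * ctn
  # spatial rotation from the first-harmonic semi-major axis
  psi <- atan2(c1[1], a1[1])
  cp <- cos(psi); sp <- sin(psi)
  a2 <- cp * a1 + sp * c1;  b2 <- cp * b1 + sp * d1
  c2 <- -sp * a1 + cp * c1; d2 <- -sp * b1 + cp * d1
  amp_x <- sqrt(a2^2 + b2^2)
  amp_y <- sqrt(c2^2 + d2^2)
  structure(list(n_harmonics = n_harmonics,
                 coeffs = cbind(a = a, b = b, c = cc, d = dd),
                 coeffs_norm = cbind(a = a2, b = b2, c = c2, d = d2),
                 A0 = A0, C0 = C0, theta = theta, psi = psi,
                 amp_x = amp_x, amp_y = amp_y,
                 amplitude = sqrt(amp_x^2 + amp_y^2),
                 band_edges = band_edges,
                 n_points_original = nrow(pts),
                 arc_length = Tt),
            class = "efd_spectrum")
}

#' @export
print.efd_spectrum <- function(x, ...) {
  cat(sprintf("<efd_spectrum> %d harmonics, total power %.4g, A(1) = %.4g\n",
              x$n_harmonics, sum(x$amplitude^2), x$amplitude[1]))
  invisible(x)
}

# harmonic index sets of the three bands, capped at the available harmonics
band_harmonics <- function(spectrum) {
  e <- pmin(spectrum$band_edges, spectrum$n_harmonics)
  list(delta = seq_len(e[1]),
       alpha = if (e[2] > e[1]) (e[1] + 1):e[2] else integer(0),
       beta  = if (e[3] > e[2]) (e[2] + 1):e[3] else integer(0))
}

#' Band powers and half-power frequency of an EFD spectrum
#'
#' Delta (harmonics 1-19), Alpha (20-55) and Beta (56-120) band powers are
#' the sums of A(f)^2 over each band; the three always partition the total
#' power exactly. The half-power frequency ("50% Frequency") is the harmonic
#' at which the cumulative spectrum reaches half of its total, linearly
#' interpolated between the bracketing harmonics. As a descriptor of the
#' outline-vs-serration balance it is accumulated over the detail spectrum
#' above the gross-ellipse fundamental (and over plain amplitudes A(f) by
#' default): with size preserved, the first harmonic otherwise carries more
#' than half of any leaf-like spectrum and the statistic degenerates to 1
#' for every leaflet. A spectrum with no detail beyond the fundamental
#' (a pure ellipse) reports 1. Squared accumulation is available as
#' `mode = "power"`.
#'
#' @param spectrum an `efd_spectrum`
#' @param mode accumulate plain amplitudes (`"amplitude"`, default) or
#'   squared amplitudes (`"power"`) for the half-power frequency
#' @return list(delta_power, alpha_power, beta_power, half_power_frequency)
#' @export
band_summary <- function(spectrum, mode = c("amplitude", "power")) {
  mode <- match.arg(mode)
  p <- spectrum$amplitude^2
  if (sum(p) <= 0) stop("zero total spectral power")
  bh <- band_harmonics(spectrum)
  acc <- if (mode == "power") p else spectrum$amplitude
  # the half-power frequency describes the outline-vs-serration balance, so
  # the accumulation runs over the detail spectrum above the gross-ellipse
  # fundamental: with size preserved, the first harmonic otherwise carries
  # more than half of any leaf-like spectrum and pins the statistic at 1
  rest <- acc[-1]
  hpf <- if (sum(rest) <= 1e-4 * sum(acc)) 1 else {
    cs <- cumsum(rest)
    target <- cs[length(cs)] / 2
    f <- which(cs >= target)[1] + 1L
    if (f <= 2) {
      1 + target / cs[1]
    } else (f - 1) + (target - cs[f - 2]) / (cs[f - 1] - cs[f - 2])
  }
  list(delta_power = sum(p[bh$delta]),
       alpha_power = sum(p[bh$alpha]),
       beta_power = sum(p[bh$beta]),
       half_power_frequency = hpf)
}

#' Inverse elliptic Fourier reconstruction from selected bands
#'
#' Rebuilds the contour in original image coordinates using only the
#' harmonics of the selected bands (all others zeroed). Delta components
#' carry the blade outline; adding Alpha restores the serration pattern;
#' Beta adds small local margin variation.
#'
#' @param spectrum an `efd_spectrum`
#' @param bands subset of `c("delta", "alpha", "beta")`, or NULL when
#'   `harmonics` is given
#' @param harmonics explicit harmonic indices (overrides `bands`)
#' @param n_out number of output points (default: the original contour size)
#' @return a `leaf_contour`
#' @export
efd_reconstruct <- function(spectrum, bands = c("delta", "alpha", "beta"),
                            harmonics = NULL, n_out = NULL) {
  if (is.null(harmonics)) {
    if (!length(bands)) stop("empty band subset")
    bands <- match.arg(bands, c("delta", "alpha", "beta"), several.ok = TRUE)
    bh <- band_harmonics(spectrum)
    harmonics <- sort(unique(unlist(bh[bands])))
  }
  harmonics <- harmonics[harmonics >= 1 & harmonics <= spectrum$n_harmonics]
  if (!length(harmonics)) stop("no harmonics selected")
  if (is.null(n_out)) n_out <- spectrum$n_points_original
  tt <- 2 * pi * (seq_len(n_out) - 1) / n_out
  co <- spectrum$coeffs[harmonics, , drop = FALSE]
  cosM <- cos(outer(tt, harmonics))          # n_out x H
  sinM <- sin(outer(tt, harmonics))
  x <- spectrum$A0 + as.numeric(cosM %*% co[, "a"] + sinM %*% co[, "b"])
  y <- spectrum$C0 + as.numeric(cosM %*% co[, "c"] + sinM %*% co[, "d"])
  leaf_contour(cbind(x, y))
}

#' Spectral low-pass outline filter
#'
#' Reconstruction from harmonics 1..cutoff. High-frequency margin detail --
#' including thin trichome spikes, which live well above the serration
#' harmonics -- is discarded while blade and tooth features are kept when
#' the cutoff is chosen above the serration band.
#'
#' @param contour a closed `leaf_contour`
#' @param cutoff_harmonic highest harmonic kept (>= 1)
#' @param n_points resampling resolution passed to [efd_transform()]
#' @return filtered `leaf_contour` with the same number of points as input
#' @export
lowpass_outline_filter <- function(contour, cutoff_harmonic, n_points = 2048) {
  if (cutoff_harmonic < 1) stop("cutoff_harmonic must be >= 1")
  sp <- efd_transform(contour, n_harmonics = cutoff_harmonic, n_points = n_points)
  efd_reconstruct(sp, harmonics = seq_len(cutoff_harmonic))
}
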