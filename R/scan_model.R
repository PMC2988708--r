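# Core scan/metadata types, digitizer-profile validation, polar geometry and
# static PPI rasterization.

SPEED_OF_LIGHT <- 299792458  # m/s, vacuum; no refraction correction applied

#' Digitizer profile
#'
#' Describes the constraints of a radar digitizing card: sample bit depth,
#' admissible digitization rates and the per-scan sample budget (pulses x
#' samples per pulse). The default profile matches a 12-bit card with rates
#' between 5 and 60 Msamples/s and at most 4 million samples per scan.
#'
#' @param bits integer bit depth of a sample (>= 1).
#' @param rate_min_hz,rate_max_hz admissible digitization rate bounds,
#'   samples/second.
#' @param sample_budget maximum pulses x samples per scan.
#' @return an object of class `digitizer_profile`.
#' @export
digitizer_profile <- function(bits = 12L, rate_min_hz = 5e6, rate_max_hz = 60e6,
                              sample_budget = 4e6) {
  stopifnot(bits >= 1, rate_min_hz > 0, rate_min_hz <= rate_max_hz,
            sample_budget >= 1)
  structure(list(bits = as.integer(bits), rate_min_hz = rate_min_hz,
                 rate_max_hz = rate_max_hz, sample_budget = sample_budget),
            class = "digitizer_profile")
}

#' Antenna configuration
#'
#' @param beam_width_deg,beam_height_deg angular beam extents (degrees, > 0).
#' @param elev_deg beam-center angle above the horizontal, in [-90, 90].
#' @param axis_tilt_deg rotation-axis tilt off vertical (degrees).
#' @param height_m antenna height above the datum (metres).
#' @return an object of class `antenna_config`.
#' @export
antenna_config <- function(beam_width_deg = 1.0, beam_height_deg = 20,
                           elev_deg = 0, axis_tilt_deg = 0, height_m = 0) {
  stopifnot(beam_width_deg > 0, beam_height_deg > 0,
            elev_deg >= -90, elev_deg <= 90)
  structure(list(beam_width_deg = beam_width_deg,
                 beam_height_deg = beam_height_deg,
                 elev_deg = elev_deg, axis_tilt_deg = axis_tilt_deg,
                 height_m = height_m),
            class = "antenna_config")
}

#' Per-scan metadata
#'
#' @param t0 timestamp of the first pulse (seconds since the Unix epoch, UTC).
#' @param n_pulses pulses digitized per rotation (matrix columns).
#' @param n_samples samples per pulse (matrix rows / range cells).
#' @param rate_hz digitization rate, samples/second.
#' @param bits sample bit depth.
#' @param prf_hz pulse repetition frequency (pulses/second).
#' @param pulse_len_s transmitted pulse length (seconds).
#' @param lat,lon radar geolocation, decimal degrees (optional, `NA` if unknown).
#' @param heading_deg azimuth of pulse 0, degrees clockwise from true north.
#' @param antenna an [antenna_config()].
#' @param duration_s rotation period (seconds).
#' @return an object of class `scan_meta`.
#' @export
scan_meta <- function(t0 = 0, n_pulses, n_samples, rate_hz, bits = 12L,
                      prf_hz = 2100, pulse_len_s = 5e-8, lat = NA_real_,
                      lon = NA_real_, heading_deg = 0,
                      antenna = antenna_config(), duration_s = 2.5) {
  stopifnot(n_pulses >= 1, n_samples >= 1, rate_hz > 0, duration_s > 0)
  structure(list(t0 = t0, n_pulses = as.integer(n_pulses),
                 n_samples = as.integer(n_samples), rate_hz = rate_hz,
                 bits = as.integer(bits), prf_hz = prf_hz,
                 pulse_len_s = pulse_len_s, lat = lat, lon = lon,
                 heading_deg = heading_deg, antenna = antenna,
                 duration_s = duration_s),
            class = "scan_meta")
}

#' Radar scan
#'
#' One full rotation of the radar, digitized as a matrix of unsigned integer
#' echo intensities with `n_samples` rows (range cells, nearest first) and
#' `n_pulses` columns (pulses, in rotation order).
#'
#' @param data integer matrix, `n_samples` x `n_pulses`.
#' @param meta a [scan_meta()].
#' @return an object of class `radar_scan`.
#' @export
radar_scan <- function(data, meta) {
  stopifnot(is.matrix(data), inherits(meta, "scan_meta"))
  if (nrow(data) != meta$n_samples || ncol(data) != meta$n_pulses)
    stop("scan data shape (", nrow(data), "x", ncol(data),
         ") does not match meta (", meta$n_samples, "x", meta$n_pulses, ")")
  structure(list(data = data, meta = meta), class = "radar_scan")
}

#' Polar geometry derived from scan metadata
#'
#' @param meta a [scan_meta()].
#' @return list with `dr_m` (range-cell depth, c/(2 rate)) and `dtheta_deg`
#'   (azimuth step, 360/n_pulses).
#' @export
polar_geometry <- function(meta) {
  dr <- SPEED_OF_LIGHT / (2 * meta$rate_hz)
  structure(list(dr_m = dr, dtheta_deg = 360 / meta$n_pulses,
                 n_samples = meta$n_samples, n_pulses = meta$n_pulses),
            class = "polar_geometry")
}

#' Admissible sample value range of a profile
#'
#' @param profile a [digitizer_profile()].
#' @return integer vector `c(min, max)` = `c(0, 2^bits - 1)`.
#' @export
sample_range <- function(profile) {
  if (profile$bits < 1) stop("invalid profile: bits must be >= 1")
  c(0, 2^profile$bits - 1)
}

#' Validate a scan against a digitizer profile
#'
#' Checks, in order: sample values within the profile's representable range,
#' pulses x samples within the sample budget, digitization rate within bounds.
#' Violations are returned as descriptors, not raised.
#'
#' @param scan a [radar_scan()].
#' @param profile a [digitizer_profile()].
#' @return list of violation descriptors, each `list(code=, message=)`;
#'   empty when valid.
#' @export
validate_scan <- function(scan, profile = digitizer_profile()) {
  v <- list()
  rng <- sample_range(profile)
  lo <- min(scan$data); hi <- max(scan$data)
  if (lo < rng[1] || hi > rng[2])
    v[[length(v) + 1]] <- list(
      code = "sample_out_of_range",
      message = sprintf("sample out of range [%d,%d]: observed [%s,%s]",
                        rng[1], rng[2], lo, hi))
  prod <- as.numeric(scan$meta$n_pulses) * scan$meta$n_samples
  if (prod > profile$sample_budget)
    v[[length(v) + 1]] <- list(
      code = "budget_exceeded",
      message = sprintf("budget exceeded: %d pulses x %d samples = %s > %s",
                        scan$meta$n_pulses, scan$meta$n_samples,
                        format(prod, scientific = FALSE),
                        format(profile$sample_budget, scientific = FALSE)))
  if (scan$meta$rate_hz < profile$rate_min_hz ||
      scan$meta$rate_hz > profile$rate_max_hz)
    v[[length(v) + 1]] <- list(
      code = "rate_out_of_bounds",
      message = sprintf("digitization rate %g Hz outside [%g,%g]",
                        scan$meta$rate_hz, profile$rate_min_hz,
                        profile$rate_max_hz))
  v
}

#' Slant range of a range cell's center
#'
#' Cell `i` (0-based) covers slant range `[i*dr, (i+1)*dr)`; its center is at
#' `(i + 0.5) * dr`.
#'
#' @param i 0-based row index (may be a vector).
#' @param geom a [polar_geometry()].
#' @return slant range in metres.
#' @export
range_of_sample <- function(i, geom) {
  if (any(i < 0) || any(i >= geom$n_samples)) stop("row index out of bounds")
  (i + 0.5) * geom$dr_m
}

#' Azimuth of a pulse column
#'
#' @param j 0-based column index (may be a vector).
#' @param meta a [scan_meta()].
#' @return azimuth in degrees clockwise from true north, in [0, 360).
#' @export
azimuth_of_pulse <- function(j, meta) {
  if (any(j < 0) || any(j >= meta$n_pulses)) stop("column index out of bounds")
  (meta$heading_deg + j * 360 / meta$n_pulses) %% 360
}

#' Project polar coordinates to local cartesian
#'
#' Ground range is `range * cos(elev)`; z uses the beam-center elevation only
#' (a single surveillance radar resolves no height within the beam).
#'
#' @param range_m slant range (metres, >= 0); vectors allowed.
#' @param azimuth_deg degrees clockwise from north.
#' @param antenna an [antenna_config()].
#' @return matrix with columns `x` (east), `y` (north), `z` (above datum), metres.
#' @export
polar_to_xyz <- function(range_m, azimuth_deg, antenna = antenna_config()) {
  stopifnot(all(range_m >= 0))
  el <- antenna$elev_deg * pi / 180
  az <- azimuth_deg * pi / 180
  g <- range_m * cos(el)
  cbind(x = g * sin(az), y = g * cos(az),
        z = antenna$height_m + range_m * sin(el))
}

#' Rasterize a scan as a plan position indicator (PPI) image
#'
#' Nearest-sample polar-to-cartesian mapping: each pixel whose center lies
#' within `rmax_m` of the radar (and within the digitized range extent) takes
#' the value of the sample whose range/azimuth cell contains it. The radar sits
#' at the image center with north up and east right. Out-of-range pixels are
#' `NA` in `values` and `FALSE` in the companion `mask`, so the raster holds
#' pure sample values.
#'
#' @param scan a [radar_scan()].
#' @param npix output image side length in pixels (>= 2).
#' @param rmax_m display radius in metres (> 0); defaults to the scan's
#'   maximum digitized range.
#' @return object of class `ppi_raster`: list with `values` (npix x npix
#'   matrix), `mask` (logical matrix, TRUE where a sample was mapped),
#'   `rmax_m`, `meta`.
#' @export
scan_to_ppi <- function(scan, npix, rmax_m = NULL) {
  meta <- scan$meta
  geom <- polar_geometry(meta)
  if (is.null(rmax_m)) rmax_m <- geom$n_samples * geom$dr_m
  if (rmax_m <= 0) stop("rmax_m must be > 0")
  stopifnot(npix >= 2)
  px <- 2 * rmax_m / npix                      # metres per pixel
  # pixel centers; row 1 at top (north), col 1 at left (west)
  xs <- (seq_len(npix) - 0.5 - npix / 2) * px
  ys <- (npix / 2 - seq_len(npix) + 0.5) * px
  x <- matrix(xs, npix, npix, byrow = TRUE)
  y <- matrix(ys, npix, npix)
  r <- sqrt(x^2 + y^2)
  az <- (atan2(x, y) * 180 / pi) %% 360
  row_idx <- floor(r / geom$dr_m) + 1
  col_idx <- floor(((az - meta$heading_deg) %% 360) / geom$dtheta_deg) + 1
  col_idx[col_idx > meta$n_pulses] <- 1L       # guard fp edge at 360
  ok <- r <= rmax_m & row_idx <= meta$n_samples
  vals <- matrix(NA_real_, npix, npix)
  vals[ok] <- scan$data[cbind(row_idx[ok], col_idx[ok])]
  structure(list(values = vals, mask = ok, rmax_m = rmax_m, meta = meta),
            class = "ppi_raster")
}

#' Write a PPI raster (or plain matrix) as a binary PGM image
#'
#' Values are rescaled linearly to 0-255; `NA` (out-of-range) pixels map to 0.
#'
#' @param x a `ppi_raster` or numeric matrix.
#' @param path output file path.
#' @param lo,hi rescaling bounds; default to the finite value range of `x`.
#' @return `path`, invisibly.
#' @export
write_pgm <- function(x, path, lo = NULL, hi = NULL) {
  m <- if (inherits(x, "ppi_raster")) x$values else x
  fv <- m[is.finite(m)]
  if (is.null(lo)) lo <- if (length(fv)) min(fv) else 0
  if (is.null(hi)) hi <- if (length(fv)) max(fv) else 1
  span <- if (hi > lo) hi - lo else 1
  g <- round(pmin(pmax((m - lo) / span, 0), 1) * 255)
  g[!is.finite(g)] <- 0
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c("P5", paste(ncol(m), nrow(m)), "255"), con)
  # PGM is row-major from the top row
  writeBin(as.raw(as.vector(t(g))), con)
  invisible(path)
}

#' Write a PPI raster as a PNG image (requires the png package)
#'
#' @inheritParams write_pgm
#' @return `path`, invisibly.
#' @export
write_ppi_png <- function(x, path, lo = NULL, hi = NULL) {
  if (!requireNamespace("png", quietly = TRUE))
    stop("the 'png' package is required for PNG output; use write_pgm()")
  m <- if (inherits(x, "ppi_raster")) x$values else x
  fv <- m[is.finite(m)]
  if (is.null(lo)) lo <- if (length(fv)) min(fv) else 0
  if (is.null(hi)) hi <- if (length(fv)) max(fv) else 1
  span <- if (hi > lo) hi - lo else 1
  g <- pmin(pmax((m - lo) / span, 0), 1)
  g[!is.finite(g)] <- 0
  png::writePNG(g, path)
  invisible(path)
}
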