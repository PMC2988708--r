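# Seeded generator of scan sequences with known ground truth: receiver noise,
# structured clutter sectors, and point targets on smooth trajectories.

#' Point-target specification
#'
#' A target moves at constant speed, either in a straight line
#' (`turn_rate_deg_s = 0`) or along a circular arc at a constant turn rate.
#' Its echo is rendered as a Gaussian point-spread blob in (range, azimuth).
#'
#' @param id target identifier (integer or character).
#' @param x0,y0 initial position, metres east/north of the radar.
#' @param vx,vy initial velocity, m/s.
#' @param turn_rate_deg_s constant turn rate, degrees/second, positive
#'   clockwise; 0 = straight line.
#' @param amplitude peak sample value added above the background (digitizer
#'   units, >= 0). Constant with range by default.
#' @param psf_sigma_r_m Gaussian point-spread sigma in range (metres, > 0).
#' @param psf_sigma_az_deg Gaussian point-spread sigma in azimuth (degrees, > 0).
#' @param range_power optional range power-law exponent `p`: the rendered
#'   amplitude is scaled by `(r_ref/r)^p` with `r_ref` = 1000 m. Default 0
#'   (no radiometric falloff), which decouples detection tests from
#'   radiometry.
#' @return object of class `target_spec`.
#' @export
target_spec <- function(id, x0, y0, vx, vy, turn_rate_deg_s = 0,
                        amplitude = 100, psf_sigma_r_m = 6,
                        psf_sigma_az_deg = 1.5, range_power = 0) {
  stopifnot(amplitude >= 0, psf_sigma_r_m > 0, psf_sigma_az_deg > 0)
  structure(list(id = id, x0 = x0, y0 = y0, vx = vx, vy = vy,
                 turn_rate_deg_s = turn_rate_deg_s, amplitude = amplitude,
                 psf_sigma_r_m = psf_sigma_r_m,
                 psf_sigma_az_deg = psf_sigma_az_deg,
                 range_power = range_power),
            class = "target_spec")
}

#' Clutter and noise specification
#'
#' Background noise is a shifted exponential: each sample is
#' `round(clip(noise_mean + Exp(scale) + additive, 0, 2^bits - 1))`. The
#' one-sided exponential mimics the intensity behavior of receiver noise and
#' clutter better than a Gaussian. A sea sector multiplies the exponential
#' scale inside an azimuth wedge; a rain blob adds a constant offset inside a
#' disc on the ground plane.
#'
#' @param noise_mean noise floor (digitizer units).
#' @param noise_scale exponential scale (digitizer units, >= 0); 0 gives a
#'   degenerate constant background.
#' @param sea_sector optional `list(az_lo, az_hi, extra_scale)`: inside
#'   `[az_lo, az_hi)` degrees the exponential scale becomes
#'   `noise_scale * (1 + extra_scale)`.
#' @param rain_blob optional `list(x, y, radius_m, extra_mean)`: samples whose
#'   cell center lies within `radius_m` of `(x, y)` get `extra_mean` added.
#' @return object of class `clutter_spec`.
#' @export
clutter_spec <- function(noise_mean = 100, noise_scale = 10,
                         sea_sector = NULL, rain_blob = NULL) {
  stopifnot(noise_scale >= 0)
  if (!is.null(sea_sector)) stopifnot(sea_sector$extra_scale >= 0)
  structure(list(noise_mean = noise_mean, noise_scale = noise_scale,
                 sea_sector = sea_sector, rain_blob = rain_blob),
            class = "clutter_spec")
}

#' Scene configuration
#'
#' @param meta_template a [scan_meta()] used for every generated scan (t0 is
#'   advanced by `duration_s` per scan).
#' @param n_scans number of scans to simulate (>= 1).
#' @param targets list of [target_spec()] objects.
#' @param clutter a [clutter_spec()].
#' @param seed RNG seed for the scene (one stream; per-scan sub-streams are
#'   derived deterministically from it).
#' @return object of class `scene_config`.
#' @export
scene_config <- function(meta_template, n_scans, targets = list(),
                         clutter = clutter_spec(), seed = 1L) {
  stopifnot(n_scans >= 1, inherits(meta_template, "scan_meta"))
  structure(list(meta_template = meta_template, n_scans = as.integer(n_scans),
                 targets = targets, clutter = clutter,
                 seed = as.integer(seed)),
            class = "scene_config")
}

# deterministic per-scan sub-seed below 2^31
scan_subseed <- function(seed, scan_index) {
  as.integer((as.numeric(seed) * 48271 + scan_index * 16807) %% 2147483647L)
}

# run fn with a locally seeded RNG, restoring the caller's RNG state
with_local_seed <- function(seed, fn) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  fn()
}

#' Generate one scan of pure noise/clutter
#'
#' @param meta a [scan_meta()].
#' @param clutter a [clutter_spec()].
#' @param seed RNG seed; identical seed gives a bitwise-identical scan.
#' @return a [radar_scan()].
#' @export
gen_noise <- function(meta, clutter = clutter_spec(), seed = 1L) {
  n <- meta$n_samples * meta$n_pulses
  scale <- rep(clutter$noise_scale, meta$n_pulses)
  if (!is.null(clutter$sea_sector)) {
    az <- azimuth_of_pulse(seq_len(meta$n_pulses) - 1, meta)
    inside <- az_in_interval(az, clutter$sea_sector$az_lo,
                             clutter$sea_sector$az_hi)
    scale[inside] <- scale[inside] * (1 + clutter$sea_sector$extra_scale)
  }
  scale_m <- matrix(scale, meta$n_samples, meta$n_pulses, byrow = TRUE)
  noise <- with_local_seed(seed, function() {
    e <- numeric(n)
    pos <- scale_m > 0
    e[pos] <- stats::rexp(sum(pos)) * scale_m[pos]
    e
  })
  vals <- clutter$noise_mean + noise
  if (!is.null(clutter$rain_blob)) {
    geom <- polar_geometry(meta)
    rb <- clutter$rain_blob
    az <- azimuth_of_pulse(seq_len(meta$n_pulses) - 1, meta) * pi / 180
    rr <- range_of_sample(seq_len(meta$n_samples) - 1, geom)
    cx <- outer(rr, sin(az))
    cy <- outer(rr, cos(az))
    hit <- (cx - rb$x)^2 + (cy - rb$y)^2 <= rb$radius_m^2
    vals[hit] <- vals[hit] + rb$extra_mean
  }
  top <- 2^meta$bits - 1
  data <- matrix(pmin(pmax(round(vals), 0), top), meta$n_samples, meta$n_pulses)
  radar_scan(data, meta)
}

# is azimuth a inside [lo, hi) modulo 360? hi - lo >= 360 means the full circle
az_in_interval <- function(a, lo, hi) {
  if (hi - lo >= 360) return(rep(TRUE, length(a)))
  (a - lo) %% 360 < (hi - lo) %% 360
}

#' Target position at time t
#'
#' Constant-velocity kinematics when `turn_rate_deg_s` is 0, otherwise a
#' circular arc at constant speed (positive turn rate = clockwise when viewed
#' from above, matching the compass heading convention).
#'
#' @param spec a [target_spec()].
#' @param t time in seconds (vector allowed, >= 0).
#' @return matrix with columns `x`, `y` (metres).
#' @export
target_position <- function(spec, t) {
  stopifnot(all(t >= 0))
  if (spec$turn_rate_deg_s == 0) {
    return(cbind(x = spec$x0 + spec$vx * t, y = spec$y0 + spec$vy * t))
  }
  w <- spec$turn_rate_deg_s * pi / 180        # rad/s, clockwise
  s <- sqrt(spec$vx^2 + spec$vy^2)
  if (s == 0) return(cbind(x = rep(spec$x0, length(t)),
                           y = rep(spec$y0, length(t))))
  th0 <- atan2(spec$vx, spec$vy)              # heading, rad cw from north
  th <- th0 + w * t
  cbind(x = spec$x0 + s / w * (cos(th0) - cos(th)),
        y = spec$y0 + s / w * (sin(th) - sin(th0)))
}

# velocity vector at time t (analytic, used for ground truth)
target_velocity <- function(spec, t) {
  if (spec$turn_rate_deg_s == 0) return(cbind(vx = spec$vx, vy = spec$vy))
  w <- spec$turn_rate_deg_s * pi / 180
  s <- sqrt(spec$vx^2 + spec$vy^2)
  th <- atan2(spec$vx, spec$vy) + w * t
  cbind(vx = s * sin(th), vy = s * cos(th))
}

# smallest absolute angular difference in degrees
ang_diff <- function(a, b) {
  d <- (a - b) %% 360
  pmin(d, 360 - d)
}

#' Render a static point target into a scan (additive)
#'
#' Adds `round(amplitude * exp(-dr^2/(2 sr^2) - dth^2/(2 sth^2)))` to every
#' cell within 3 sigma of the target in range and azimuth (azimuth with
#' wraparound across the 0/360 seam), clipping at the bit-depth ceiling.
#' Positions beyond the scan's maximum range are a no-op.
#'
#' @param scan a [radar_scan()].
#' @param pos numeric `c(x, y)` position, metres.
#' @param spec a [target_spec()].
#' @return the modified [radar_scan()].
#' @export
render_target <- function(scan, pos, spec) {
  meta <- scan$meta
  render_target_fn(scan, function(t) matrix(pos, 1), spec, t_ref = meta$t0)
}

# Render a (possibly moving) target: pos_fn(t) returns 1-row (x,y) for scalar t,
# evaluated at each pulse's own transmit time so fast targets smear
# realistically.
render_target_fn <- function(scan, pos_fn, spec, t_ref = scan$meta$t0) {
  meta <- scan$meta
  geom <- polar_geometry(meta)
  top <- 2^meta$bits - 1
  np <- meta$n_pulses; ns <- meta$n_samples
  tj <- t_ref + (seq_len(np) - 1) * meta$duration_s / np
  p <- t(vapply(tj, function(t) as.numeric(pos_fn(t)[1, 1:2]), numeric(2)))
  rt <- sqrt(p[, 1]^2 + p[, 2]^2)
  azt <- (atan2(p[, 1], p[, 2]) * 180 / pi) %% 360
  azj <- azimuth_of_pulse(seq_len(np) - 1, meta)
  dth <- ang_diff(azj, azt)
  cols <- which(dth <= 3 * spec$psf_sigma_az_deg & rt < ns * geom$dr_m)
  if (!length(cols)) return(scan)
  data <- scan$data
  for (j in cols) {
    amp <- spec$amplitude
    if (spec$range_power != 0 && rt[j] > 0)
      amp <- amp * (1000 / rt[j])^spec$range_power
    gz <- amp * exp(-dth[j]^2 / (2 * spec$psf_sigma_az_deg^2))
    i0 <- max(1, floor((rt[j] - 3 * spec$psf_sigma_r_m) / geom$dr_m) + 1)
    i1 <- min(ns, floor((rt[j] + 3 * spec$psf_sigma_r_m) / geom$dr_m) + 1)
    if (i1 < i0) next
    rows <- i0:i1
    dr <- range_of_sample(rows - 1, geom) - rt[j]
    add <- round(gz * exp(-dr^2 / (2 * spec$psf_sigma_r_m^2)))
    data[rows, j] <- pmin(data[rows, j] + add, top)
  }
  radar_scan(data, meta)
}

# ground-truth record for one target in one scan: the position at the moment
# the rotating beam crosses the target (fixed-point iteration from the scan
# midpoint), plus the polar cell that position falls in.
truth_for_target <- function(spec, meta, scan_index) {
  geom <- polar_geometry(meta)
  t0 <- meta$t0     # already advanced to this scan's start
  t <- t0 + meta$duration_s / 2
  for (iter in 1:8) {
    p <- target_position(spec, t)
    az <- (atan2(p[1, 1], p[1, 2]) * 180 / pi) %% 360
    j <- floor(((az - meta$heading_deg) %% 360) / geom$dtheta_deg)
    t_new <- t0 + j * meta$duration_s / meta$n_pulses
    if (abs(t_new - t) < 1e-9) { t <- t_new; break }
    t <- t_new
  }
  p <- target_position(spec, t)
  r <- sqrt(p[1, 1]^2 + p[1, 2]^2)
  az <- (atan2(p[1, 1], p[1, 2]) * 180 / pi) %% 360
  i <- floor(r / geom$dr_m)
  j <- floor(((az - meta$heading_deg) %% 360) / geom$dtheta_deg)
  v <- target_velocity(spec, t)
  data.frame(scan = scan_index, target_id = as.character(spec$id), t = t,
             x = p[1, 1], y = p[1, 2], vx = v[1, 1], vy = v[1, 2],
             row = i, col = j, in_range = i < meta$n_samples,
             stringsAsFactors = FALSE)
}

#' Simulate a scene of scans with known ground truth
#'
#' Scan `s` (0-based) starts at `t0 + s * duration_s`. Targets are evaluated at
#' each pulse's own transmit time, so fast targets smear across azimuth
#' realistically. The ground truth records, for every (scan, target) pair, the
#' target position at the moment the beam crosses it and the polar cell it
#' falls in.
#'
#' @param config a [scene_config()].
#' @return list with `scans` (list of [radar_scan()]) and `truth` (data.frame
#'   with columns scan, target_id, t, x, y, vx, vy, row, col, in_range;
#'   scan and row/col are 0-based).
#' @export
simulate_scene <- function(config) {
  meta0 <- config$meta_template
  scans <- vector("list", config$n_scans)
  truth <- list()
  for (s in seq_len(config$n_scans) - 1) {
    meta <- meta0
    meta$t0 <- meta0$t0 + s * meta0$duration_s
    scan <- gen_noise(meta, config$clutter, seed = scan_subseed(config$seed, s))
    for (tg in config$targets) {
      scan <- render_target_fn(scan, function(t) target_position(tg, t), tg,
                               t_ref = meta$t0)
      truth[[length(truth) + 1]] <- truth_for_target(tg, meta, s)
    }
    scans[[s + 1]] <- scan
  }
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(scan = integer(), target_id = character(), t = numeric(),
               x = numeric(), y = numeric(), vx = numeric(), vy = numeric(),
               row = integer(), col = integer(), in_range = logical())
  list(scans = scans, truth = truth)
}

#' Write a scene's ground truth as CSV
#'
#' @param truth the `truth` data.frame from [simulate_scene()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
export_truth <- function(truth, path) {
  utils::write.csv(truth, path, row.names = FALSE)
  invisible(path)
}
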