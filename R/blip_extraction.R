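# Adaptive background model, z-score thresholding, patch grouping, blip
# properties and filtering.

#' Stats-cell grid
#'
#' The unit over which background mean and deviation are pooled: a rectangular
#' window of `cell_rows` samples (range direction) by `cell_cols` pulses.
#' When scan dimensions are not divisible by the cell dimensions, the last cell
#' in each direction absorbs the remainder.
#'
#' @param cell_rows,cell_cols window extents, both >= 1.
#' @return object of class `stats_grid`.
#' @export
stats_grid <- function(cell_rows = 32L, cell_cols = 32L) {
  stopifnot(cell_rows >= 1, cell_cols >= 1)
  structure(list(cell_rows = as.integer(cell_rows),
                 cell_cols = as.integer(cell_cols)),
            class = "stats_grid")
}

# 1-based stats-cell index for each row (or col) of a scan dimension
cell_index <- function(n, cell_size) {
  ncell <- max(1L, n %/% cell_size)
  pmin((seq_len(n) - 1L) %/% cell_size + 1L, ncell)
}

# per-cell mean and mean absolute deviation of a pool of scans (list of
# matrices), as ncellrow x ncellcol matrices
pooled_cell_stats <- function(mats, grid, estimator = "mad") {
  nr <- nrow(mats[[1]]); nc <- ncol(mats[[1]])
  ri <- cell_index(nr, grid$cell_rows)
  ci <- cell_index(nc, grid$cell_cols)
  nri <- max(ri); nci <- max(ci)
  fac <- ri + nri * (rep(ci, each = nr) - 1L)   # cell id per sample
  counts <- tabulate(fac, nri * nci) * length(mats)
  sums <- numeric(nri * nci)
  for (mm in mats) sums <- sums + rowsum(as.numeric(mm), fac, reorder = TRUE)[, 1]
  m <- sums / counts
  dev <- numeric(nri * nci)
  for (mm in mats) {
    delta <- as.numeric(mm) - m[fac]
    if (estimator == "mad") dev <- dev + rowsum(abs(delta), fac, reorder = TRUE)[, 1]
    else dev <- dev + rowsum(delta^2, fac, reorder = TRUE)[, 1]
  }
  d <- if (estimator == "mad") dev / counts else sqrt(dev / counts)
  list(m = matrix(m, nri, nci), d = matrix(d, nri, nci),
       row_index = ri, col_index = ci)
}

#' Learn the background model from a sequence of scans
#'
#' For each stats cell, pools every sample in the cell across all learning
#' scans and computes the pooled mean `m` and the mean absolute deviation `d`
#' about it (`estimator = "sd"` substitutes the standard deviation).
#'
#' @param scans list of [radar_scan()] objects, all the same shape.
#' @param grid a [stats_grid()].
#' @param estimator `"mad"` (mean absolute deviation, default) or `"sd"`.
#' @return object of class `background_model` with per-cell matrices `m`, `d`.
#' @export
learn_background <- function(scans, grid = stats_grid(), estimator = c("mad", "sd")) {
  estimator <- match.arg(estimator)
  if (!length(scans)) stop("empty scan list")
  dims <- vapply(scans, function(s) dim(s$data), integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("shape mismatch among learning scans")
  st <- pooled_cell_stats(lapply(scans, `[[`, "data"), grid, estimator)
  structure(list(grid = grid, m = st$m, d = st$d,
                 row_index = st$row_index, col_index = st$col_index,
                 n_learned = length(scans), estimator = estimator),
            class = "background_model")
}

#' Intensity z-score against cell statistics
#'
#' `d > 0` gives the usual `(x - m)/d`; a degenerate cell (`d = 0`) scores
#' `+Inf` above the mean, `-Inf` below and `0` at it, so any sample above a
#' constant background is hot at any finite threshold.
#'
#' @param x sample value(s).
#' @param m,d cell mean and deviation (recycled).
#' @return numeric z-score(s).
#' @export
zscore <- function(x, m, d) {
  z <- (x - m) / d
  deg <- d == 0
  if (any(deg)) {
    delta <- (x - m)[deg]
    z[deg] <- ifelse(delta > 0, Inf, ifelse(delta < 0, -Inf, 0))
  }
  z
}

#' Hot-sample mask of a scan against the background
#'
#' A sample is hot when its z-score strictly exceeds `z_thresh`.
#'
#' @param scan a [radar_scan()].
#' @param bg a [background_model()][learn_background].
#' @param z_thresh hot threshold in z-score units.
#' @return logical matrix, same shape as the scan.
#' @export
find_hot <- function(scan, bg, z_thresh) {
  if (length(bg$row_index) != nrow(scan$data) ||
      length(bg$col_index) != ncol(scan$data))
    stop("scan shape incompatible with background model")
  m <- bg$m[bg$row_index, bg$col_index, drop = FALSE]
  d <- bg$d[bg$row_index, bg$col_index, drop = FALSE]
  z <- zscore(scan$data, m, d)
  z > z_thresh
}

#' Group hot samples into patches
#'
#' Patches are maximal 8-connected components of the hot mask; the first and
#' last pulse columns are adjacent (azimuth wraparound) but there is no
#' wraparound in range. Output is sorted by (min row, min unwrapped column).
#'
#' @param mask logical matrix (rows = range cells, cols = pulses).
#' @return list of patches; each is a list with `cells` (matrix with columns
#'   row, col, 1-based) and `bbox` (`c(row_min, row_max, col_min, col_max)`,
#'   columns unwrapped: a seam-crossing patch has `col_min` <= 0).
#' @export
group_patches <- function(mask) {
  hot <- which(mask)
  if (!length(hot)) return(list())
  nr <- nrow(mask); nc <- ncol(mask)
  row <- ((hot - 1L) %% nr) + 1L
  col <- ((hot - 1L) %/% nr) + 1L
  # forward neighbour offsets (drow, dcol); col wraps, row does not
  offs <- rbind(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))
  edges <- integer(0)
  key <- function(r, cc) (cc - 1) * nr + r
  idx_of <- integer(0)
  hot_key <- key(row, col)
  for (k in seq_len(nrow(offs))) {
    r2 <- row + offs[k, 1]
    c2 <- ((col - 1L + offs[k, 2]) %% nc) + 1L
    ok <- r2 >= 1 & r2 <= nr
    if (nc == 1) ok <- ok & offs[k, 2] == 0L   # no self-wrap on single column
    j <- match(key(r2[ok], c2[ok]), hot_key)
    from <- which(ok)[!is.na(j)]
    to <- j[!is.na(j)]
    keep <- from != to                          # guard 2-column double wrap
    edges <- c(edges, rbind(from[keep], to[keep]))
  }
  g <- igraph::make_graph(edges, n = length(hot), directed = FALSE)
  comp <- igraph::components(g)$membership
  patches <- lapply(split(seq_along(hot), comp), function(ix) {
    cells <- cbind(row = row[ix], col = col[ix],
                   value = rep(NA_real_, length(ix)))
    ucol <- unwrap_cols(col[ix], nc)
    list(cells = cells,
         bbox = c(row_min = min(row[ix]), row_max = max(row[ix]),
                  col_min = min(ucol), col_max = max(ucol)))
  })
  ord <- order(vapply(patches, function(p) p$bbox[["row_min"]], numeric(1)),
               vapply(patches, function(p) p$bbox[["col_min"]], numeric(1)))
  unname(patches[ord])
}

# unwrap a set of columns (1-based) that may cross the seam: columns after the
# largest circular gap are taken as the start; earlier ones shift down by nc.
# Returns possibly non-positive column values whose span reflects adjacency.
unwrap_cols <- function(cols, nc) {
  u <- sort(unique(cols))
  if (length(u) == nc) return(cols)            # full circle: leave as-is
  gaps <- diff(c(u, u[1] + nc))                # circular gaps
  gi <- which.max(gaps)
  start <- u[(gi %% length(u)) + 1]            # first column after biggest gap
  ((cols - start) %% nc) + start
}

#' Compute the summary properties of a patch
#'
#' @param patch a patch from [group_patches()] (its `value` column may be NA;
#'   values are taken from `scan`).
#' @param scan the [radar_scan()] the patch came from.
#' @return object of class `blip`: the patch cells (with values) plus `t`
#'   (timestamp, s), centroid `x`, `y`, `z` (m), `n_samples`, `area_m2`,
#'   `perimeter_cells`, `int_mean`, `int_max`, `angular_span_deg`,
#'   `radial_span_m`.
#' @export
blip_properties <- function(patch, scan) {
  meta <- scan$meta
  geom <- polar_geometry(meta)
  r <- patch$cells[, "row"]; cc <- patch$cells[, "col"]
  vals <- scan$data[cbind(r, cc)]
  n <- length(vals)
  rng <- range_of_sample(r - 1, geom)
  az <- azimuth_of_pulse(cc - 1, meta)
  xyz <- polar_to_xyz(rng, az, meta$antenna)
  w <- vals / sum(vals)
  cx <- sum(w * xyz[, 1]); cy <- sum(w * xyz[, 2])
  rbar <- sum(w * rng)
  cz <- meta$antenna$height_m + rbar * sin(meta$antenna$elev_deg * pi / 180)
  dth_rad <- geom$dtheta_deg * pi / 180
  area <- sum(rng * dth_rad * geom$dr_m)
  ucol <- unwrap_cols(cc, meta$n_pulses)
  # perimeter: cells with >= 1 of 4 neighbours (col wraps) outside the patch
  keyset <- (cc - 1) * meta$n_samples + r
  out_any <- rep(FALSE, n)
  for (off in list(c(1L, 0L), c(-1L, 0L), c(0L, 1L), c(0L, -1L))) {
    r2 <- r + off[1]
    c2 <- ((cc - 1L + off[2]) %% meta$n_pulses) + 1L
    outside <- r2 < 1 | r2 > meta$n_samples |
      is.na(match((c2 - 1) * meta$n_samples + r2, keyset))
    out_any <- out_any | outside
  }
  perim <- sum(out_any)
  t_blip <- meta$t0 + mean(ucol - 1) * meta$duration_s / meta$n_pulses
  structure(list(
    cells = cbind(row = r, col = cc, value = vals),
    t = t_blip, x = cx, y = cy, z = cz,
    n_samples = n, area_m2 = area, perimeter_cells = perim,
    int_mean = mean(vals), int_max = max(vals),
    angular_span_deg = length(unique(cc)) * geom$dtheta_deg,
    radial_span_m = length(unique(r)) * geom$dr_m),
    class = "blip")
}

#' Blip filtering criteria
#'
#' Closed (inclusive) bounds on blip properties, each optional, plus an
#' optional user predicate receiving the blip and returning TRUE to keep it.
#'
#' @param min_samples,max_samples bounds on number of samples.
#' @param min_area_m2,max_area_m2 bounds on PPI area.
#' @param min_angular_deg,max_angular_deg bounds on angular span.
#' @param min_radial_m,max_radial_m bounds on radial span.
#' @param predicate optional `function(blip) -> logical`.
#' @return object of class `blip_filters`.
#' @export
blip_filters <- function(min_samples = NULL, max_samples = NULL,
                         min_area_m2 = NULL, max_area_m2 = NULL,
                         min_angular_deg = NULL, max_angular_deg = NULL,
                         min_radial_m = NULL, max_radial_m = NULL,
                         predicate = NULL) {
  chk <- function(lo, hi) is.null(lo) || is.null(hi) || lo <= hi
  stopifnot(chk(min_samples, max_samples), chk(min_area_m2, max_area_m2),
            chk(min_angular_deg, max_angular_deg), chk(min_radial_m, max_radial_m))
  structure(list(min_samples = min_samples, max_samples = max_samples,
                 min_area_m2 = min_area_m2, max_area_m2 = max_area_m2,
                 min_angular_deg = min_angular_deg,
                 max_angular_deg = max_angular_deg,
                 min_radial_m = min_radial_m, max_radial_m = max_radial_m,
                 predicate = predicate),
            class = "blip_filters")
}

blip_passes <- function(b, f) {
  within <- function(v, lo, hi)
    (is.null(lo) || v >= lo) && (is.null(hi) || v <= hi)
  within(b$n_samples, f$min_samples, f$max_samples) &&
    within(b$area_m2, f$min_area_m2, f$max_area_m2) &&
    within(b$angular_span_deg, f$min_angular_deg, f$max_angular_deg) &&
    within(b$radial_span_m, f$min_radial_m, f$max_radial_m) &&
    (is.null(f$predicate) || isTRUE(f$predicate(b)))
}

#' Filter blips by user criteria
#'
#' @param blips list of [blip_properties()] objects.
#' @param filters a [blip_filters()].
#' @return the surviving blips, in their original (stable) order.
#' @export
filter_blips <- function(blips, filters = blip_filters()) {
  blips[vapply(blips, blip_passes, logical(1), f = filters)]
}

#' Update the background model with one scan
#'
#' Exponentially weighted update at decay rate `alpha`: per stats cell,
#' `m <- (1-alpha) m + alpha m_scan` and `d <- (1-alpha) d + alpha d_scan`,
#' where `m_scan`, `d_scan` are that single scan's pooled cell statistics.
#' All samples are included by default; pass the scan's hot `mask` with
#' `exclude_hot = TRUE` to update from non-hot samples only (cells that are
#' entirely hot are left unchanged).
#'
#' @param bg a background model.
#' @param scan a [radar_scan()].
#' @param alpha decay rate in [0, 1]; 0 leaves the model unchanged, 1 replaces
#'   it with the single-scan statistics.
#' @param exclude_hot logical.
#' @param mask hot mask (required when `exclude_hot`).
#' @return the updated background model.
#' @export
update_background <- function(bg, scan, alpha, exclude_hot = FALSE, mask = NULL) {
  stopifnot(alpha >= 0, alpha <= 1)
  if (alpha == 0) return(bg)
  dat <- scan$data
  if (exclude_hot) {
    stopifnot(!is.null(mask))
    dat[mask] <- NA_real_
  }
  ri <- bg$row_index; ci <- bg$col_index
  nri <- nrow(bg$m); nci <- ncol(bg$m)
  fac <- ri + nri * (rep(ci, each = nrow(dat)) - 1L)
  v <- as.numeric(dat)
  okv <- !is.na(v)
  counts <- tabulate(fac[okv], nri * nci)
  sums <- rowsum(v[okv], fac[okv], reorder = TRUE)
  m_scan <- rep(NA_real_, nri * nci)
  m_scan[as.integer(rownames(sums))] <- sums[, 1] / counts[as.integer(rownames(sums))]
  delta <- abs(v - m_scan[fac])
  if (bg$estimator == "sd") delta <- (v - m_scan[fac])^2
  dsum <- rowsum(delta[okv], fac[okv], reorder = TRUE)
  d_scan <- rep(NA_real_, nri * nci)
  d_scan[as.integer(rownames(dsum))] <- dsum[, 1] / counts[as.integer(rownames(dsum))]
  if (bg$estimator == "sd") d_scan <- sqrt(d_scan)
  m_scan <- matrix(m_scan, nri, nci)
  d_scan <- matrix(d_scan, nri, nci)
  upd <- !is.na(m_scan)
  bg$m[upd] <- (1 - alpha) * bg$m[upd] + alpha * m_scan[upd]
  bg$d[upd] <- (1 - alpha) * bg$d[upd] + alpha * d_scan[upd]
  bg
}

#' Sector processing rule
#'
#' @param az_lo,az_hi azimuth interval `[az_lo, az_hi)` degrees (wraparound
#'   allowed; must be nonempty mod 360).
#' @param r_lo,r_hi slant-range interval, metres.
#' @param action `"discard"` (drop data in the sector) or `"override"`
#'   (re-filter blips in the sector with `filters`).
#' @param filters a [blip_filters()], required for `"override"`.
#' @return object of class `sector_rule`.
#' @export
sector_rule <- function(az_lo, az_hi, r_lo = 0, r_hi = Inf,
                        action = c("discard", "override"), filters = NULL) {
  action <- match.arg(action)
  if ((az_hi - az_lo) %% 360 == 0 && az_hi - az_lo < 360)
    stop("empty azimuth interval")
  if (action == "override" && is.null(filters))
    stop("override sector requires filters")
  structure(list(az_lo = az_lo, az_hi = az_hi, r_lo = r_lo, r_hi = r_hi,
                 action = action, filters = filters),
            class = "sector_rule")
}

blip_in_sector <- function(b, sec, meta) {
  g <- sqrt(b$x^2 + b$y^2)
  el <- meta$antenna$elev_deg * pi / 180
  r <- if (cos(el) > 0) g / cos(el) else g
  az <- (atan2(b$x, b$y) * 180 / pi) %% 360
  az_in_interval(az, sec$az_lo, sec$az_hi) && r >= sec$r_lo && r <= sec$r_hi
}

#' Apply sector rules to a hot mask and/or a blip list
#'
#' Discard sectors zero the mask inside the sector and drop blips whose
#' centroid falls inside. Override sectors re-apply their filters to blips
#' whose centroid falls inside; when override sectors overlap, the
#' first-listed sector wins.
#'
#' @param blips list of blips (or NULL to transform only the mask).
#' @param mask hot mask (or NULL to transform only blips).
#' @param sectors list of [sector_rule()] objects.
#' @param meta the scan's [scan_meta()].
#' @return list with possibly modified `blips` and `mask`.
#' @export
apply_sector_rules <- function(blips, mask, sectors, meta) {
  if (!length(sectors)) return(list(blips = blips, mask = mask))
  geom <- polar_geometry(meta)
  if (!is.null(mask)) {
    az <- azimuth_of_pulse(seq_len(meta$n_pulses) - 1, meta)
    rr <- range_of_sample(seq_len(meta$n_samples) - 1, geom)
    for (sec in sectors) {
      if (sec$action != "discard") next
      cols <- az_in_interval(az, sec$az_lo, sec$az_hi)
      rows <- rr >= sec$r_lo & rr <= sec$r_hi
      mask[rows, cols] <- FALSE
    }
  }
  if (!is.null(blips) && length(blips)) {
    keep <- logical(length(blips))
    for (bi in seq_along(blips)) {
      b <- blips[[bi]]
      verdict <- TRUE
      for (sec in sectors) {
        if (!blip_in_sector(b, sec, meta)) next
        verdict <- if (sec$action == "discard") FALSE
                   else blip_passes(b, sec$filters)
        break                                   # first-listed sector wins
      }
      keep[bi] <- verdict
    }
    blips <- blips[keep]
  }
  list(blips = blips, mask = mask)
}

#' Extraction parameters
#'
#' @param z_thresh hot threshold, z-score units.
#' @param learn_scans number of scans used to initialize the background.
#' @param alpha background decay rate in [0, 1].
#' @param update_enabled update the background after each processed scan?
#' @param exclude_hot exclude hot samples from background updates?
#' @param filters a [blip_filters()].
#' @param sectors list of [sector_rule()] objects.
#' @param grid a [stats_grid()].
#' @param estimator background deviation estimator, `"mad"` or `"sd"`.
#' @return object of class `extraction_params`.
#' @export
extraction_params <- function(z_thresh = 4, learn_scans = 4L, alpha = 0.1,
                              update_enabled = TRUE, exclude_hot = FALSE,
                              filters = blip_filters(), sectors = list(),
                              grid = stats_grid(), estimator = "mad") {
  stopifnot(alpha >= 0, alpha <= 1, learn_scans >= 1, is.finite(z_thresh))
  structure(list(z_thresh = z_thresh, learn_scans = as.integer(learn_scans),
                 alpha = alpha, update_enabled = update_enabled,
                 exclude_hot = exclude_hot, filters = filters,
                 sectors = sectors, grid = grid, estimator = estimator),
            class = "extraction_params")
}

#' Extract blips from one scan
#'
#' Full per-scan pipeline: hot mask, sector discards on the mask, patch
#' grouping, blip properties, blip filtering, sector rules on blips, then an
#' optional background update. Blips are returned sorted by (t, centroid
#' azimuth).
#'
#' @param scan a [radar_scan()].
#' @param bg a learned background model.
#' @param params an [extraction_params()].
#' @return list with `blips` (sorted list of blips) and `bg` (updated model).
#' @export
extract_blips <- function(scan, bg, params) {
  mask <- find_hot(scan, bg, params$z_thresh)
  mask <- apply_sector_rules(NULL, mask, params$sectors, scan$meta)$mask
  patches <- group_patches(mask)
  blips <- lapply(patches, blip_properties, scan = scan)
  blips <- filter_blips(blips, params$filters)
  blips <- apply_sector_rules(blips, NULL, params$sectors, scan$meta)$blips
  if (length(blips)) {
    az <- vapply(blips, function(b) (atan2(b$x, b$y) * 180 / pi) %% 360,
                 numeric(1))
    ts <- vapply(blips, `[[`, numeric(1), "t")
    blips <- blips[order(ts, az)]
  }
  if (params$update_enabled)
    bg <- update_background(bg, scan, params$alpha,
                            exclude_hot = params$exclude_hot, mask = mask)
  list(blips = blips, bg = bg)
}
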