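# Background learning, z-scores, patch grouping, blip properties, filtering.

test_that("learn_background pools cells across scans (constant and two-level cases)", {
  meta <- small_meta(n_pulses = 8, n_samples = 8)
  bg <- learn_background(list(const_scan(100, meta), const_scan(100, meta)),
                         stats_grid(4, 4))
  expect_true(all(bg$m == 100))
  expect_true(all(bg$d == 0))
  bg2 <- learn_background(list(const_scan(90, meta), const_scan(110, meta)),
                          stats_grid(4, 4))
  expect_true(all(bg2$m == 100))
  expect_true(all(bg2$d == 10))     # mean |x - 100| over {90, 110}
  expect_error(learn_background(list()), "empty")
  expect_error(learn_background(list(const_scan(1, meta),
                                     const_scan(1, small_meta(4, 4)))),
               "shape mismatch")
})

test_that("learn_background equals the naive pooled-loop oracle, remainder cells included", {
  set.seed(31)
  for (dims in list(c(16L, 16L, 4L, 4L), c(17L, 19L, 4L, 8L),
                    c(8L, 8L, 3L, 5L))) {
    meta <- small_meta(n_pulses = dims[2], n_samples = dims[1])
    scans <- lapply(1:3, function(i)
      radar_scan(matrix(sample.int(4096, dims[1] * dims[2], TRUE) - 1L,
                        dims[1], dims[2]), meta))
    bg <- learn_background(scans, stats_grid(dims[3], dims[4]))
    or <- oracle_pooled_stats(lapply(scans, `[[`, "data"), dims[3], dims[4])
    expect_equal(bg$m, or$m)
    expect_equal(bg$d, or$d)
  }
})

test_that("zscore handles the degenerate zero-deviation cell", {
  expect_equal(zscore(100, 100, 10), 0)
  expect_equal(zscore(130, 100, 10), 3)
  expect_equal(zscore(101, 100, 0), Inf)
  expect_equal(zscore(99, 100, 0), -Inf)
  expect_equal(zscore(100, 100, 0), 0)
  expect_equal(zscore(c(90, 100, 110), 100, c(10, 0, 0)), c(-1, 0, Inf))
})

test_that("find_hot matches elementwise recomputation and uses strict inequality", {
  meta <- small_meta(n_pulses = 16, n_samples = 16)
  scans <- lapply(1:2, function(i) {
    set.seed(40 + i)
    radar_scan(matrix(sample.int(200, 256, TRUE) + 50L, 16, 16), meta)
  })
  bg <- learn_background(scans, stats_grid(4, 4))
  s <- scans[[1]]
  mask <- find_hot(s, bg, 1.5)
  m_full <- bg$m[bg$row_index, bg$col_index]
  d_full <- bg$d[bg$row_index, bg$col_index]
  oracle <- matrix(FALSE, 16, 16)
  for (i in 1:16) for (j in 1:16)
    oracle[i, j] <- zscore(s$data[i, j], m_full[i, j], d_full[i, j]) > 1.5
  expect_identical(mask, oracle)
  # scan equal to the background mean is never hot at a positive threshold
  flat <- radar_scan(matrix(round(m_full), 16, 16), meta)
  bgc <- learn_background(list(flat), stats_grid(4, 4))
  expect_false(any(find_hot(flat, bgc, 3)))
  # exactly one sample at m + 5d with z_thresh 3
  bg5 <- learn_background(list(const_scan(90, meta), const_scan(110, meta)),
                          stats_grid(4, 4))
  dat <- matrix(100L, 16, 16); dat[7, 9] <- 150L  # z = 5
  expect_equal(which(find_hot(radar_scan(dat, meta), bg5, 3)),
               which(matrix(seq_len(256), 16, 16) == (9 - 1) * 16 + 7))
})

test_that("group_patches matches a flood-fill oracle on random masks and joins the seam", {
  # single cell
  m1 <- matrix(FALSE, 8, 8); m1[3, 4] <- TRUE
  p1 <- group_patches(m1)
  expect_length(p1, 1)
  expect_equal(unname(p1[[1]]$cells[, c("row", "col")]), c(3, 4))
  # seam join across the first/last column
  m2 <- matrix(FALSE, 8, 8); m2[5, 1] <- TRUE; m2[5, 8] <- TRUE
  expect_length(group_patches(m2), 1)
  # empty mask
  expect_length(group_patches(matrix(FALSE, 4, 4)), 0)
  # 50 random 16x16 masks vs the oracle
  set.seed(99)
  for (trial in 1:50) {
    mask <- matrix(runif(256) < runif(1, 0.05, 0.5), 16, 16)
    got <- canon_sets(patch_sets(group_patches(mask), 16))
    want <- canon_sets(component_sets(oracle_flood_fill(mask)))
    expect_identical(got, want)
  }
})

test_that("group_patches output is sorted by (min row, min unwrapped col)", {
  m <- matrix(FALSE, 10, 10)
  m[7, 2] <- TRUE          # later row
  m[2, 5] <- TRUE          # first by row
  m[2, 9] <- TRUE
  p <- group_patches(m)
  expect_equal(vapply(p, function(x) x$bbox[["row_min"]], numeric(1)),
               c(2, 2, 7))
  expect_equal(p[[1]]$cells[1, "col"][[1]], 5)
})

test_that("blip_properties computes area, spans, perimeter and centroid from polar geometry", {
  meta <- small_meta(n_pulses = 64, n_samples = 64)
  geom <- polar_geometry(meta)
  dth <- geom$dtheta_deg * pi / 180
  # single-cell patch at row i
  i <- 10L; j <- 5L
  dat <- matrix(100L, 64, 64)
  s <- radar_scan(dat, meta)
  p <- list(cells = cbind(row = i + 1, col = j + 1, value = NA))
  b <- blip_properties(p, s)
  expect_equal(b$n_samples, 1)
  expect_equal(b$area_m2, (i + 0.5) * geom$dr_m^2 * dth)
  expect_equal(b$perimeter_cells, 1)
  expect_equal(b$angular_span_deg, geom$dtheta_deg)
  expect_equal(b$radial_span_m, geom$dr_m)
  expect_equal(b$int_mean, 100); expect_equal(b$int_max, 100)
  expect_equal(b$t, meta$t0 + j * meta$duration_s / 64)
  # 2x2 equal-value block: perimeter 4, centroid at the geometric mean position
  rows <- c(20L, 21L, 20L, 21L); cols <- c(8L, 8L, 9L, 9L)
  p2 <- list(cells = cbind(row = rows, col = cols, value = NA))
  b2 <- blip_properties(p2, s)
  expect_equal(b2$perimeter_cells, 4)
  xyz <- polar_to_xyz(range_of_sample(rows - 1, geom),
                      azimuth_of_pulse(cols - 1, meta), meta$antenna)
  expect_equal(b2$x, mean(xyz[, 1]))
  expect_equal(b2$y, mean(xyz[, 2]))
  # L-shaped 3-cell patch: perimeter 3, area = sum of its single-cell areas
  rows3 <- c(30L, 31L, 31L); cols3 <- c(4L, 4L, 5L)
  b3 <- blip_properties(list(cells = cbind(row = rows3, col = cols3,
                                           value = NA)), s)
  expect_equal(b3$perimeter_cells, 3)
  expect_equal(b3$area_m2,
               sum(range_of_sample(rows3 - 1, geom) * dth * geom$dr_m))
  expect_equal(b3$n_samples, 3)
})

test_that("filter_blips keeps blips inside all closed bounds, stable order; oracle check", {
  meta <- small_meta(n_pulses = 32, n_samples = 32)
  s <- const_scan(100, meta)
  mk <- function(cells) blip_properties(list(cells = cells), s)
  ones <- lapply(c(2, 12, 22), function(r)
    mk(cbind(row = r, col = 5, value = NA)))
  threes <- lapply(c(6, 16), function(r)
    mk(cbind(row = c(r, r + 1, r + 2), col = 7, value = NA)))
  blips <- c(ones[1], threes[1], ones[2], threes[2], ones[3])
  expect_identical(filter_blips(blips, blip_filters()), blips)
  kept <- filter_blips(blips, blip_filters(min_samples = 2))
  expect_length(kept, 2)
  expect_true(all(vapply(kept, `[[`, numeric(1), "n_samples") == 3))
  # randomized bounds vs per-blip re-check
  set.seed(5)
  for (trial in 1:20) {
    f <- blip_filters(
      min_samples = sample(0:3, 1), max_samples = sample(3:9, 1),
      min_area_m2 = runif(1, 0, 50), max_area_m2 = runif(1, 50, 5000),
      min_radial_m = runif(1, 0, 5), max_radial_m = runif(1, 5, 50))
    got <- filter_blips(blips, f)
    want <- blips[vapply(blips, function(b)
      b$n_samples >= f$min_samples && b$n_samples <= f$max_samples &&
        b$area_m2 >= f$min_area_m2 && b$area_m2 <= f$max_area_m2 &&
        b$radial_span_m >= f$min_radial_m &&
        b$radial_span_m <= f$max_radial_m, logical(1))]
    expect_identical(got, want)
  }
  # user predicate hook
  far <- filter_blips(blips, blip_filters(predicate = function(b) b$y > 40))
  expect_true(all(vapply(far, `[[`, numeric(1), "y") > 40))
})

test_that("update_background follows the exponential decay closed form and its fixed point", {
  meta <- small_meta(n_pulses = 8, n_samples = 8)
  scans <- list(const_scan(90, meta), const_scan(110, meta))
  bg <- learn_background(scans, stats_grid(4, 4))
  # alpha = 0 leaves the model untouched
  s <- const_scan(200, meta)
  expect_identical(update_background(bg, s, 0), bg)
  # alpha = 1 replaces it with single-scan stats
  bg1 <- update_background(bg, s, 1)
  expect_true(all(bg1$m == 200) && all(bg1$d == 0))
  # n repeated updates with a constant scan: m = (1-a)^n m0 + (1-(1-a)^n) s
  a <- 0.3; m0 <- 100
  bgn <- bg
  for (n in 1:6) bgn <- update_background(bgn, s, a)
  expect_equal(unique(as.vector(bgn$m)),
               (1 - a)^6 * m0 + (1 - (1 - a)^6) * 200, tolerance = 1e-12)
  # fixed point: updating with a scan whose cell stats equal the model's
  # leaves (m, d) unchanged for any alpha -- constant-cell case has d = 0
  bgc <- learn_background(list(const_scan(100, meta)), stats_grid(4, 4))
  for (a in c(0.1, 0.5, 1)) {
    upd <- update_background(bgc, const_scan(100, meta), a)
    expect_equal(upd$m, bgc$m); expect_equal(upd$d, bgc$d)
  }
  # excluded hot samples do not move the background
  mask <- matrix(FALSE, 8, 8); mask[1:4, 1:4] <- TRUE
  sh <- const_scan(100, meta); sh$data[1:4, 1:4] <- 4000L
  bgx <- update_background(bgc, sh, 0.5, exclude_hot = TRUE, mask = mask)
  expect_true(all(bgx$m == 100))
})

test_that("sector rules discard mask regions and blips, first-listed sector wins", {
  meta <- small_meta(n_pulses = 64, n_samples = 64)
  s <- const_scan(100, meta)
  mask <- matrix(TRUE, 64, 64)
  # empty rules are the identity
  r0 <- apply_sector_rules(list(), mask, list(), meta)
  expect_identical(r0$mask, mask)
  sec <- sector_rule(180, 360, action = "discard")
  az <- azimuth_of_pulse(0:63, meta)
  r1 <- apply_sector_rules(NULL, mask, list(sec), meta)
  expect_true(all(!r1$mask[, az >= 180]))
  expect_true(all(r1$mask[, az < 180]))
  # blips with centroid azimuth >= 180 are dropped
  mkb <- function(col) blip_properties(
    list(cells = cbind(row = 30, col = col, value = NA)), s)
  blips <- lapply(c(1L, 17L, 33L, 49L), mkb)   # az 0, 90, 180, 270
  r2 <- apply_sector_rules(blips, NULL, list(sec), meta)$blips
  azb <- vapply(r2, function(b) (atan2(b$x, b$y) * 180 / pi) %% 360,
                numeric(1))
  expect_true(all(azb < 180))
  expect_length(r2, 2)
  # overlapping override sectors: the first listed wins
  s1 <- sector_rule(0, 360, action = "override",
                    filters = blip_filters(min_samples = 1))
  s2 <- sector_rule(0, 360, action = "override",
                    filters = blip_filters(min_samples = 99))
  keep_first <- apply_sector_rules(blips, NULL, list(s1, s2), meta)$blips
  expect_length(keep_first, 4)   # first rule admits everything
  drop_first <- apply_sector_rules(blips, NULL, list(s2, s1), meta)$blips
  expect_length(drop_first, 0)
})

test_that("extract_blips equals the manual composition of its stages", {
  meta <- small_meta(n_pulses = 64, n_samples = 64)
  tg <- target_spec("A", 60, 60, 4, 1, amplitude = 400, psf_sigma_r_m = 6,
                    psf_sigma_az_deg = 6)
  cfg <- scene_config(meta, 5, list(tg), clutter_spec(), seed = 8)
  sim <- simulate_scene(cfg)
  pars <- extraction_params(z_thresh = 4, learn_scans = 3, alpha = 0.2,
                            filters = blip_filters(min_samples = 3),
                            sectors = list(sector_rule(350, 355,
                                                       action = "discard")))
  bg <- learn_background(sim$scans[1:3], pars$grid)
  s <- sim$scans[[4]]
  got <- extract_blips(s, bg, pars)
  # manual composition
  mask <- find_hot(s, bg, pars$z_thresh)
  mask <- apply_sector_rules(NULL, mask, pars$sectors, meta)$mask
  blips <- lapply(group_patches(mask), blip_properties, scan = s)
  blips <- filter_blips(blips, pars$filters)
  blips <- apply_sector_rules(blips, NULL, pars$sectors, meta)$blips
  az <- vapply(blips, function(b) (atan2(b$x, b$y) * 180 / pi) %% 360,
               numeric(1))
  ts <- vapply(blips, `[[`, numeric(1), "t")
  blips <- blips[order(ts, az)]
  bg2 <- update_background(bg, s, pars$alpha)
  expect_identical(got$blips, blips)
  expect_equal(got$bg$m, bg2$m)
  expect_equal(got$bg$d, bg2$d)
  # scan equal to the learned background: zero blips
  flat <- const_scan(100, meta)
  bgf <- learn_background(list(flat), stats_grid())
  expect_length(extract_blips(flat, bgf, pars)$blips, 0)
})

test_that("retained blip cells are hot cells and patches partition the mask", {
  meta <- small_meta(n_pulses = 64, n_samples = 64)
  tg <- target_spec("A", 60, 60, 4, 1, amplitude = 400, psf_sigma_r_m = 6,
                    psf_sigma_az_deg = 6)
  sim <- simulate_scene(scene_config(meta, 4, list(tg), clutter_spec(),
                                     seed = 77))
  bg <- learn_background(sim$scans[1:3], stats_grid())
  s <- sim$scans[[4]]
  mask <- find_hot(s, bg, 4)
  patches <- group_patches(mask)
  all_cells <- sort(unlist(patch_sets(patches, 64)))
  expect_identical(all_cells, sort(which(mask)))  # partition
  res <- extract_blips(s, bg, extraction_params(
    z_thresh = 4, update_enabled = FALSE, filters = blip_filters(min_samples = 2)))
  for (b in res$blips)
    expect_true(all(mask[b$cells[, c("row", "col"), drop = FALSE]]))
})

test_that("raising z_thresh never increases hot-sample or blip counts", {
  meta <- small_meta(n_pulses = 64, n_samples = 64)
  tg <- target_spec("A", 60, 60, 4, 1, amplitude = 300, psf_sigma_r_m = 6,
                    psf_sigma_az_deg = 6)
  sim <- simulate_scene(scene_config(meta, 4, list(tg), clutter_spec(),
                                     seed = 13))
  bg <- learn_background(sim$scans[1:3], stats_grid())
  s <- sim$scans[[4]]
  thresholds <- c(1, 2, 3, 4, 6)
  hots <- blipn <- numeric(length(thresholds))
  for (i in seq_along(thresholds)) {
    hots[i] <- sum(find_hot(s, bg, thresholds[i]))
    blipn[i] <- length(extract_blips(s, bg, extraction_params(
      z_thresh = thresholds[i], update_enabled = FALSE))$blips)
  }
  expect_true(all(diff(hots) <= 0))
  expect_true(all(diff(blipn) <= 0))
})
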