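# Shared fixtures and independent oracles for the test suite.

# small scan metadata used across tests
small_meta <- function(n_pulses = 64L, n_samples = 128L, rate_hz = 50e6,
                       duration_s = 2.5, heading_deg = 0, ...) {
  scan_meta(n_pulses = n_pulses, n_samples = n_samples, rate_hz = rate_hz,
            duration_s = duration_s, heading_deg = heading_deg, ...)
}

const_scan <- function(value, meta = small_meta()) {
  radar_scan(matrix(value, meta$n_samples, meta$n_pulses), meta)
}

# --- independent oracles -----------------------------------------------------

# naive pooled per-cell mean / mean absolute deviation by explicit double loop
oracle_pooled_stats <- function(mats, cell_rows, cell_cols) {
  nr <- nrow(mats[[1]]); nc <- ncol(mats[[1]])
  nri <- max(1, nr %/% cell_rows); nci <- max(1, nc %/% cell_cols)
  m <- matrix(0, nri, nci); d <- matrix(0, nri, nci)
  for (i in seq_len(nri)) {
    rows <- ((i - 1) * cell_rows + 1):(if (i == nri) nr else i * cell_rows)
    for (j in seq_len(nci)) {
      cols <- ((j - 1) * cell_cols + 1):(if (j == nci) nc else j * cell_cols)
      pool <- unlist(lapply(mats, function(mm) as.numeric(mm[rows, cols])))
      m[i, j] <- mean(pool)
      d[i, j] <- mean(abs(pool - m[i, j]))
    }
  }
  list(m = m, d = d)
}

# flood-fill connected components: 8-connectivity, column wraparound
oracle_flood_fill <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  nxt <- 0L
  for (r0 in seq_len(nr)) for (c0 in seq_len(nc)) {
    if (!mask[r0, c0] || lab[r0, c0] != 0L) next
    nxt <- nxt + 1L
    queue <- list(c(r0, c0))
    lab[r0, c0] <- nxt
    while (length(queue)) {
      cur <- queue[[1]]; queue <- queue[-1]
      for (dr in -1:1) for (dc in -1:1) {
        if (dr == 0 && dc == 0) next
        r <- cur[1] + dr
        cc <- ((cur[2] - 1 + dc) %% nc) + 1
        if (r < 1 || r > nr) next
        if (mask[r, cc] && lab[r, cc] == 0L) {
          lab[r, cc] <- nxt
          queue[[length(queue) + 1]] <- c(r, cc)
        }
      }
    }
  }
  lab
}

# components as canonical sets of cell keys, for order-independent comparison
component_sets <- function(lab) {
  ks <- which(lab != 0)
  sets <- split(ks, lab[ks])
  unname(lapply(sets, sort))
}

patch_sets <- function(patches, nr) {
  unname(lapply(patches, function(p)
    sort(as.integer((p$cells[, "col"] - 1) * nr + p$cells[, "row"]))))
}

canon_sets <- function(sets) sets[order(vapply(sets, `[`, numeric(1), 1))]

# exhaustive minimum-total-distance maximum-cardinality matching
oracle_assignment <- function(pairs) {
  tr <- unique(pairs$track); bl <- unique(pairs$blip)
  best <- list(card = -1L, cost = Inf)
  # enumerate all injective partial maps track -> blip present in pairs
  rec <- function(i, used_bl, card, cost) {
    if (i > length(tr)) {
      if (card > best$card || (card == best$card && cost < best$cost - 1e-12))
        best <<- list(card = card, cost = cost)
      return(invisible())
    }
    # skip this track
    rec(i + 1, used_bl, card, cost)
    sub <- pairs[pairs$track == tr[i], , drop = FALSE]
    for (r in seq_len(nrow(sub))) {
      b <- sub$blip[r]
      if (b %in% used_bl) next
      rec(i + 1, c(used_bl, b), card + 1L, cost + sub$dist[r])
    }
  }
  rec(1L, integer(0), 0L, 0)
  best
}

# minimal hand-made blip for tracker tests
mk_blip <- function(x, y, t, z = 0, area = 100, int_mean = 50) {
  structure(list(cells = cbind(row = 1, col = 1, value = int_mean),
                 t = t, x = x, y = y, z = z, n_samples = 1, area_m2 = area,
                 perimeter_cells = 1, int_mean = int_mean, int_max = int_mean,
                 angular_span_deg = 1, radial_span_m = 3),
            class = "blip")
}

mk_track <- function(blips, scans, id = 1L) {
  list(id = id, blips = blips, scans = as.integer(scans), state = "active",
       created_scan = scans[1], last_update_scan = scans[length(scans)])
}

# Constructed crossing geometry: target A moves east at 4 m/s along y = 0,
# target B moves south at 3 m/s along x = 8, meeting A's path at scan 3.
# At scan 3 the NN assignment (minimum total extension distance) swaps the
# targets (swap total 0 + 5 beats the correct 4 + 3); the MFC
# velocity-homogeneity gain keeps them apart.
crossing_blips <- function() {
  a <- lapply(0:4, function(s) mk_blip(4 * s, 0, s))
  b <- lapply(0:4, function(s) mk_blip(8, 9 - 3 * s, s + 0.01))
  lapply(0:4, function(s) list(a[[s + 1]], b[[s + 1]]))
}

# straight-line blip sequence: one blip per scan at constant velocity
straight_blips <- function(n, x0 = 0, y0 = 0, vx = 10, vy = 0, dt = 1,
                           t0 = 0) {
  lapply(seq_len(n) - 1, function(i)
    mk_blip(x0 + vx * i * dt, y0 + vy * i * dt, t0 + i * dt))
}
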