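# Track-while-scan linking of blips across scans: nearest-neighbour (NN)
# assignment minimizing total extension distance, and a greedy multiframe
# correspondence (MFC) linker maximizing a proximity/velocity-homogeneity gain
# over a sliding window of k scans.

#' Tracker parameters
#'
#' @param max_speed_mps maximum admissible speed for a track extension.
#' @param max_turn_deg maximum turning angle between consecutive segments.
#' @param max_rel_change maximum relative change in blip area (or mean
#'   intensity, see `rel_change_on`) between consecutive blips, as a fraction.
#' @param rel_change_on `"area"` (default) or `"int_mean"`.
#' @param expiry_scans E: unmatched blips are dropped from the seeding pool,
#'   and unextended tracks complete, after more than E scans without a match.
#' @param k MFC window length in scans (>= 2); links older than k scans are
#'   frozen and cannot be retroactively broken.
#' @param w_prox,w_vel gain weights for the proximity and velocity-homogeneity
#'   terms (>= 0).
#' @param sigma_p_m,sigma_v_mps gain scale constants (metres, m/s; > 0).
#' @param gain_min feasibility floor: candidate extensions with gain below
#'   this are discarded by the MFC linker.
#' @param gap_penalty gain penalty per scan skipped by a candidate link
#'   (log-gain units). A link that jumps over a scan — after a missed
#'   detection, or because it breaks off a trailing blip — must beat the
#'   competing gap-free extensions by this much per skipped scan; without it,
#'   longer-baseline predictions are smoother and noise alone makes breaking
#'   profitable.
#' @param link_reward value of completing a link (log-gain units). Extensions
#'   are ranked at `link_reward + gain`; a break is ranked by its net effect
#'   `gain_new - gain_old` (the reward of the broken and remade link cancels),
#'   so an existing link is only broken when it is worse than the replacement
#'   by more than the reward. Without a positive reward, every link has
#'   non-positive gain and removing one always "improves" the total.
#' @param gain_fn optional user hook `function(track, blip, params)` replacing
#'   the default [gain()].
#' @param rng_seed seed for tie-breaking "coin tosses"; identical inputs and
#'   seed give identical tracks.
#' @return object of class `tracker_params`.
#' @export
tracker_params <- function(max_speed_mps = Inf, max_turn_deg = 180,
                           max_rel_change = Inf,
                           rel_change_on = c("area", "int_mean"),
                           expiry_scans = 1L, k = 3L, w_prox = 1, w_vel = 1,
                           sigma_p_m = 25, sigma_v_mps = 5, gain_min = -10,
                           gap_penalty = 0.5, link_reward = 1,
                           gain_fn = NULL, rng_seed = 1L) {
  rel_change_on <- match.arg(rel_change_on)
  stopifnot(expiry_scans >= 1, k >= 2, w_prox >= 0, w_vel >= 0,
            sigma_p_m > 0, sigma_v_mps > 0, gap_penalty >= 0,
            link_reward >= 0)
  structure(list(max_speed_mps = max_speed_mps, max_turn_deg = max_turn_deg,
                 max_rel_change = max_rel_change, rel_change_on = rel_change_on,
                 expiry_scans = as.integer(expiry_scans), k = as.integer(k),
                 w_prox = w_prox, w_vel = w_vel, sigma_p_m = sigma_p_m,
                 sigma_v_mps = sigma_v_mps, gain_min = gain_min,
                 gap_penalty = gap_penalty, link_reward = link_reward,
                 gain_fn = gain_fn, rng_seed = as.integer(rng_seed)),
            class = "tracker_params")
}

blip_xyz <- function(b) c(b$x, b$y, b$z)
dist3 <- function(a, b) sqrt(sum((blip_xyz(a) - blip_xyz(b))^2))

# bearing (degrees cw from north) of the 2-D displacement a -> b; NA if zero
bearing <- function(a, b) {
  dx <- b$x - a$x; dy <- b$y - a$y
  if (dx == 0 && dy == 0) return(NA_real_)
  (atan2(dx, dy) * 180 / pi) %% 360
}

#' New empty tracker state
#'
#' @param type `"nn"` or `"mfc"`.
#' @param params a [tracker_params()].
#' @return object of class `tracker_state`.
#' @export
new_tracker <- function(type = c("nn", "mfc"), params = tracker_params()) {
  type <- match.arg(type)
  structure(list(type = type, params = params, tracks = list(),
                 pool = list(), scan_counter = -1L, next_id = 1L,
                 completed_this_step = integer(0)),
            class = "tracker_state")
}

#' Features of a candidate track-blip pair
#'
#' @param track a track (list with `blips`, time-ordered).
#' @param blip a candidate [blip_properties()] object with `t` after the
#'   track's last blip.
#' @param rel_change_on `"area"` or `"int_mean"`.
#' @return named numeric: `distance_m` (3-D Euclidean from the track's last
#'   blip), `speed_mps`, `turn_deg` (0 for 1-blip tracks or degenerate
#'   segments), `rel_change`.
#' @export
pair_features <- function(track, blip, rel_change_on = "area") {
  last <- track$blips[[length(track$blips)]]
  dt <- blip$t - last$t
  if (dt <= 0) stop("candidate blip does not follow the track in time")
  d <- dist3(last, blip)
  turn <- 0
  if (length(track$blips) >= 2) {
    prev <- track$blips[[length(track$blips) - 1]]
    h1 <- bearing(prev, last); h2 <- bearing(last, blip)
    if (!is.na(h1) && !is.na(h2)) turn <- ang_diff(h1, h2)
  }
  fld <- if (rel_change_on == "area") "area_m2" else "int_mean"
  rc <- abs(blip[[fld]] - last[[fld]]) / last[[fld]]
  c(distance_m = d, speed_mps = d / dt, turn_deg = turn, rel_change = rc)
}

pair_ok <- function(f, params) {
  f[["speed_mps"]] <= params$max_speed_mps &&
    f[["turn_deg"]] <= params$max_turn_deg &&
    f[["rel_change"]] <= params$max_rel_change
}

#' Feasible track-blip pairs
#'
#' All (active track, new blip) pairs whose speed, turn and relative change
#' fall within the parameter bounds (inclusive).
#'
#' @param state a [new_tracker()] state.
#' @param blips list of blips from one scan.
#' @param params a [tracker_params()].
#' @return data.frame with columns `track` (index into `state$tracks`),
#'   `blip` (index into `blips`), `dist` (extension distance, m).
#' @export
feasible_pairs <- function(state, blips, params = state$params) {
  out <- list()
  for (ti in seq_along(state$tracks)) {
    tr <- state$tracks[[ti]]
    if (tr$state != "active") next
    for (bi in seq_along(blips)) {
      if (blips[[bi]]$t <= tr$blips[[length(tr$blips)]]$t) next
      f <- pair_features(tr, blips[[bi]], params$rel_change_on)
      if (pair_ok(f, params))
        out[[length(out) + 1]] <- data.frame(track = ti, blip = bi,
                                             dist = f[["distance_m"]])
    }
  }
  if (!length(out)) return(data.frame(track = integer(), blip = integer(),
                                      dist = numeric()))
  do.call(rbind, out)
}

#' Minimum-total-distance assignment of blips to tracks
#'
#' Among the feasible pairs, finds a matching of maximum cardinality that
#' minimizes the total extension distance (each track and blip used at most
#' once). Exact ties between optimal matchings are broken by a seeded
#' permutation of the candidates (the "coin toss"), so results are
#' deterministic given the seed.
#'
#' @param pairs data.frame with columns `track`, `blip`, `dist` (ids may be
#'   arbitrary integers).
#' @param seed tie-break seed (optional).
#' @return data.frame with columns `track`, `blip`, `dist` — the matching.
#' @export
assign_min_cost <- function(pairs, seed = NULL) {
  if (!nrow(pairs)) return(pairs)
  ord <- seq_len(nrow(pairs))
  if (!is.null(seed)) ord <- with_local_seed(seed, function() sample(ord))
  p <- pairs[ord, , drop = FALSE]
  tr_ids <- unique(p$track); bl_ids <- unique(p$blip)
  nt <- length(tr_ids); nb <- length(bl_ids)
  ti <- match(p$track, tr_ids); bi <- match(p$blip, bl_ids)
  big <- (min(nt, nb) + 1) * (max(p$dist) + 1)
  g <- igraph::make_bipartite_graph(c(rep(FALSE, nt), rep(TRUE, nb)),
                                    edges = as.vector(rbind(ti, nt + bi)))
  m <- igraph::max_bipartite_match(g, weights = big - p$dist,
                                   eps = 1e-9 * big)
  mate <- m$matching[seq_len(nt)]
  matched <- which(!is.na(mate))
  if (!length(matched)) return(pairs[0, , drop = FALSE])
  res <- data.frame(track = tr_ids[matched], blip = bl_ids[mate[matched] - nt])
  # recover distances of the matched pairs
  key <- paste(res$track, res$blip)
  res$dist <- pairs$dist[match(key, paste(pairs$track, pairs$blip))]
  res
}

make_track <- function(state, blips, scans) {
  id <- state$next_id
  list(id = id, blips = blips, scans = as.integer(scans), state = "active",
       created_scan = scans[1], last_update_scan = scans[length(scans)])
}

# shared post-step bookkeeping: seed new tracks from the unmatched pool,
# refresh the pool, expire tracks
finish_step <- function(state, blips, unmatched_bi, scan_index, params) {
  # pair unmatched new blips with pool blips to seed 2-blip tracks
  if (length(unmatched_bi) && length(state$pool)) {
    cand <- list()
    for (pi in seq_along(state$pool)) {
      pe <- state$pool[[pi]]
      for (bi in unmatched_bi) {
        b <- blips[[bi]]
        dt <- b$t - pe$blip$t
        if (dt <= 0) next
        d <- dist3(pe$blip, b)
        fld <- if (params$rel_change_on == "area") "area_m2" else "int_mean"
        rc <- abs(b[[fld]] - pe$blip[[fld]]) / pe$blip[[fld]]
        if (d / dt <= params$max_speed_mps && rc <= params$max_rel_change)
          cand[[length(cand) + 1]] <- data.frame(track = pi, blip = bi, dist = d)
      }
    }
    if (length(cand)) {
      m <- assign_min_cost(do.call(rbind, cand),
                           seed = params$rng_seed + 7L * scan_index + 3L)
      for (r in seq_len(nrow(m))) {
        pe <- state$pool[[m$track[r]]]
        tr <- make_track(state, list(pe$blip, blips[[m$blip[r]]]),
                         c(pe$scan, scan_index))
        state$tracks[[length(state$tracks) + 1]] <- tr
        state$next_id <- state$next_id + 1L
      }
      state$pool[unique(m$track)] <- NULL
      unmatched_bi <- setdiff(unmatched_bi, m$blip)
    }
  }
  for (bi in unmatched_bi)
    state$pool[[length(state$pool) + 1]] <- list(blip = blips[[bi]],
                                                 scan = scan_index)
  if (length(state$pool)) {
    age <- vapply(state$pool, function(p) scan_index - p$scan, numeric(1))
    state$pool <- state$pool[age <= params$expiry_scans]
  }
  state$completed_this_step <- integer(0)
  for (ti in seq_along(state$tracks)) {
    tr <- state$tracks[[ti]]
    if (tr$state == "active" &&
        scan_index - tr$last_update_scan > params$expiry_scans) {
      state$tracks[[ti]]$state <- "complete"
      state$completed_this_step <- c(state$completed_this_step, tr$id)
    }
  }
  state$scan_counter <- as.integer(scan_index)
  state
}

#' Advance the nearest-neighbour tracker by one scan
#'
#' Matches the scan's blips to active tracks with [assign_min_cost()], seeds
#' new 2-blip tracks from the unmatched pool, ages the pool, and completes
#' tracks unextended for more than `expiry_scans` scans.
#'
#' @param state a [new_tracker()] state.
#' @param blips blips of one scan (list).
#' @param scan_index integer scan counter (0-based, strictly increasing).
#' @param params a [tracker_params()]; defaults to the state's.
#' @return the updated state.
#' @export
step_nn <- function(state, blips, scan_index, params = state$params) {
  fp <- feasible_pairs(state, blips, params)
  m <- assign_min_cost(fp, seed = params$rng_seed + 7L * scan_index)
  matched_bi <- integer(0)
  for (r in seq_len(nrow(m))) {
    ti <- m$track[r]; bi <- m$blip[r]
    tr <- state$tracks[[ti]]
    tr$blips[[length(tr$blips) + 1]] <- blips[[bi]]
    tr$scans <- c(tr$scans, as.integer(scan_index))
    tr$last_update_scan <- as.integer(scan_index)
    state$tracks[[ti]] <- tr
    matched_bi <- c(matched_bi, bi)
  }
  finish_step(state, blips, setdiff(seq_along(blips), matched_bi),
              scan_index, params)
}

#' Match-quality gain of extending a track with a blip
#'
#' A weighted sum on a log scale of (i) proximity of the blip to the position
#' predicted by the track's last velocity (constant-velocity prediction) and
#' (ii) velocity homogeneity when the blip is appended:
#' `gain = -w_prox*ln(1 + d/sigma_p) - w_vel*ln(1 + dv/sigma_v)`,
#' bounded above by 0 (a blip exactly at the prediction with unchanged
#' velocity).
#'
#' @param track a track with at least 2 blips (velocity defined).
#' @param blip candidate blip with `t` after the track's last blip.
#' @param params a [tracker_params()] (set `gain_fn` there to replace this).
#' @return scalar gain (<= 0 for the default form).
#' @export
gain <- function(track, blip, params = tracker_params()) {
  if (!is.null(params$gain_fn)) return(params$gain_fn(track, blip, params))
  n <- length(track$blips)
  stopifnot(n >= 2)
  b1 <- track$blips[[n - 1]]; b2 <- track$blips[[n]]
  dt_last <- b2$t - b1$t
  v_last <- (blip_xyz(b2) - blip_xyz(b1)) / dt_last
  dt <- blip$t - b2$t
  if (dt <= 0) stop("candidate blip does not follow the track in time")
  pred <- blip_xyz(b2) + v_last * dt
  d <- sqrt(sum((blip_xyz(blip) - pred)^2))
  v_new <- (blip_xyz(blip) - blip_xyz(b2)) / dt
  dv <- sqrt(sum((v_new - v_last)^2))
  -params$w_prox * log(1 + d / params$sigma_p_m) -
    params$w_vel * log(1 + dv / params$sigma_v_mps)
}

#' Advance the multiframe-correspondence tracker by one scan
#'
#' Until a track with a defined velocity exists, steps fall back to the NN
#' linker (the bootstrap). Afterwards, every feasible extension of every
#' active track — including extensions that break an existing link within the
#' sliding window of the last `k` scans — is ranked by [gain()] (less
#' `gap_penalty` per skipped scan; break candidates count the gain of the
#' link they destroy against themselves, so the ranking maximizes the total
#' gain) and accepted greedily without conflicts. Broken-off multi-blip track
#' tails become new tracks and, together with unmatched blips, take part in a
#' second matching phase; single orphaned blips return to the unmatched pool.
#' Links older than `k` scans are frozen.
#'
#' @inheritParams step_nn
#' @return the updated state.
#' @export
step_mfc <- function(state, blips, scan_index, params = state$params) {
  has_vel <- any(vapply(state$tracks, function(tr)
    tr$state == "active" && length(tr$blips) >= 2, logical(1)))
  if (!has_vel) return(step_nn(state, blips, scan_index, params))

  # phase 1: candidate (track, cut, blip, gain) triples
  cand <- list()
  for (ti in seq_along(state$tracks)) {
    tr <- state$tracks[[ti]]
    if (tr$state != "active") next
    if (scan_index - tr$last_update_scan > params$expiry_scans) next
    len <- length(tr$blips)
    cuts <- len
    if (len > 2) {
      # earlier cuts break links; only links within the last k scans may break
      breakable <- which(tr$scans > scan_index - params$k)
      breakable <- breakable[breakable >= 3]   # prefix must keep >= 2 blips
      cuts <- unique(c(len, breakable - 1L))
    }
    for (cpos in cuts) {
      prefix <- list(blips = tr$blips[seq_len(cpos)],
                     scans = tr$scans[seq_len(cpos)])
      # breaking destroys the existing link out of the prefix; a break
      # candidate is ranked by its net effect on the total gain
      g_old <- 0
      if (cpos < len)
        g_old <- gain(prefix, tr$blips[[cpos + 1]], params) -
          params$gap_penalty * (tr$scans[cpos + 1] - tr$scans[cpos] - 1L)
      for (bi in seq_along(blips)) {
        b <- blips[[bi]]
        if (b$t <= prefix$blips[[cpos]]$t) next
        f <- pair_features(prefix, b, params$rel_change_on)
        if (!pair_ok(f, params)) next
        skipped <- max(0L, scan_index - prefix$scans[cpos] - 1L)
        g <- gain(prefix, b, params) - params$gap_penalty * skipped
        if (g < params$gain_min) next
        rank <- if (cpos == len) params$link_reward + g else g - g_old
        az <- (atan2(b$x, b$y) * 180 / pi) %% 360
        cand[[length(cand) + 1]] <-
          data.frame(track = ti, cut = cpos, blip = bi, gain = rank,
                     tid = tr$id, az = az)
      }
    }
  }
  matched_bi <- integer(0)
  tails <- list()
  if (length(cand)) {
    cd <- do.call(rbind, cand)
    coin <- with_local_seed(params$rng_seed + 13L * scan_index,
                            function() stats::runif(nrow(cd)))
    # ties (gains equal to 1e-9): prefer pure extension over breaking (larger
    # cut), then track id, blip azimuth, and finally a seeded coin toss
    cd <- cd[order(-round(cd$gain, 9), -cd$cut, cd$tid, cd$az, coin),
             , drop = FALSE]
    used_tr <- logical(length(state$tracks))
    used_bl <- logical(length(blips))
    for (r in seq_len(nrow(cd))) {
      ti <- cd$track[r]; bi <- cd$blip[r]; cpos <- cd$cut[r]
      if (used_tr[ti] || used_bl[bi]) next
      used_tr[ti] <- TRUE; used_bl[bi] <- TRUE
      tr <- state$tracks[[ti]]
      if (cpos < length(tr$blips)) {
        tails[[length(tails) + 1]] <-
          list(blips = tr$blips[(cpos + 1):length(tr$blips)],
               scans = tr$scans[(cpos + 1):length(tr$scans)])
        tr$blips <- tr$blips[seq_len(cpos)]
        tr$scans <- tr$scans[seq_len(cpos)]
      }
      tr$blips[[length(tr$blips) + 1]] <- blips[[bi]]
      tr$scans <- c(tr$scans, as.integer(scan_index))
      tr$last_update_scan <- as.integer(scan_index)
      state$tracks[[ti]] <- tr
      matched_bi <- c(matched_bi, bi)
    }
  }
  # phase 2: multi-blip broken-off tails become tracks and may claim
  # unmatched blips; single orphaned blips go back to the unmatched pool
  tail_idx <- integer(0)
  for (tl in tails) {
    if (length(tl$blips) == 1) {
      state$pool[[length(state$pool) + 1]] <- list(blip = tl$blips[[1]],
                                                   scan = tl$scans[1])
      next
    }
    tr <- make_track(state, tl$blips, tl$scans)
    state$tracks[[length(state$tracks) + 1]] <- tr
    state$next_id <- state$next_id + 1L
    tail_idx <- c(tail_idx, length(state$tracks))
  }
  unmatched_bi <- setdiff(seq_along(blips), matched_bi)
  if (length(tail_idx) && length(unmatched_bi)) {
    cand2 <- list()
    for (ti in tail_idx) {
      tr <- state$tracks[[ti]]
      for (bi in unmatched_bi) {
        b <- blips[[bi]]
        if (b$t <= tr$blips[[length(tr$blips)]]$t) next
        f <- pair_features(tr, b, params$rel_change_on)
        if (pair_ok(f, params))
          cand2[[length(cand2) + 1]] <-
            data.frame(track = ti, blip = bi, dist = f[["distance_m"]])
      }
    }
    if (length(cand2)) {
      m <- assign_min_cost(do.call(rbind, cand2),
                           seed = params$rng_seed + 13L * scan_index + 5L)
      for (r in seq_len(nrow(m))) {
        ti <- m$track[r]; bi <- m$blip[r]
        tr <- state$tracks[[ti]]
        tr$blips[[length(tr$blips) + 1]] <- blips[[bi]]
        tr$scans <- c(tr$scans, as.integer(scan_index))
        tr$last_update_scan <- as.integer(scan_index)
        state$tracks[[ti]] <- tr
        unmatched_bi <- setdiff(unmatched_bi, bi)
      }
    }
  }
  finish_step(state, blips, unmatched_bi, scan_index, params)
}

#' Run a tracker over a sequence of per-scan blip lists
#'
#' @param blips_by_scan list of per-scan blip lists.
#' @param type `"nn"` or `"mfc"`.
#' @param params a [tracker_params()].
#' @param scan_offset scan index of the first element (default 0).
#' @return final `tracker_state`; all tracks are marked complete.
#' @export
track_blips <- function(blips_by_scan, type = c("nn", "mfc"),
                        params = tracker_params(), scan_offset = 0L) {
  type <- match.arg(type)
  state <- new_tracker(type, params)
  stepf <- if (type == "nn") step_nn else step_mfc
  for (s in seq_along(blips_by_scan))
    state <- stepf(state, blips_by_scan[[s]], scan_offset + s - 1L, params)
  for (ti in seq_along(state$tracks))
    state$tracks[[ti]]$state <- "complete"
  state
}

#' Score recovered tracks against simulated ground truth
#'
#' A recovered link (two consecutive blips of one estimated track) is correct
#' when both blips fall within `match_radius_m` (2-D) of the same truth target
#' at their scans and those truth detections are consecutive. Precision is
#' correct/estimated links (1.0 when no links are claimed); recall is
#' correct/truth links; purity is each track's majority-target blip fraction,
#' averaged over tracks with at least one blip.
#'
#' @param state a `tracker_state` (or list of tracks with `blips`, `scans`).
#' @param truth ground-truth data.frame from [simulate_scene()].
#' @param match_radius_m association radius, metres.
#' @return named list: `link_precision`, `link_recall`, `track_purity`,
#'   `n_links_est`, `n_links_truth`, `n_links_correct`.
#' @export
evaluate_tracks <- function(state, truth, match_radius_m) {
  if (!nrow(truth)) stop("empty ground truth")
  tracks <- if (inherits(state, "tracker_state")) state$tracks else state
  tr_truth <- truth[truth$in_range, , drop = FALSE]
  assign_target <- function(b, scan) {
    cand <- tr_truth[tr_truth$scan == scan, , drop = FALSE]
    if (!nrow(cand)) return(NA_character_)
    d <- sqrt((cand$x - b$x)^2 + (cand$y - b$y)^2)
    if (min(d) > match_radius_m) return(NA_character_)
    cand$target_id[which.min(d)]
  }
  # truth links: consecutive in-range detections per target
  n_truth_links <- 0L
  truth_consec <- new.env()
  for (tid in unique(tr_truth$target_id)) {
    ss <- sort(tr_truth$scan[tr_truth$target_id == tid])
    if (length(ss) >= 2) {
      n_truth_links <- n_truth_links + length(ss) - 1L
      assign(tid, ss, envir = truth_consec)
    }
  }
  n_est <- 0L; n_correct <- 0L
  purities <- numeric(0)
  for (tr in tracks) {
    nb <- length(tr$blips)
    if (!nb) next
    tg <- vapply(seq_len(nb),
                 function(i) assign_target(tr$blips[[i]], tr$scans[i]),
                 character(1))
    tab <- table(tg[!is.na(tg)])
    purities <- c(purities, if (length(tab)) max(tab) / nb else 0)
    if (nb < 2) next
    for (i in seq_len(nb - 1)) {
      n_est <- n_est + 1L
      if (is.na(tg[i]) || is.na(tg[i + 1]) || tg[i] != tg[i + 1]) next
      ss <- get(tg[i], envir = truth_consec)
      pos <- match(tr$scans[i], ss)
      if (!is.na(pos) && pos < length(ss) && ss[pos + 1] == tr$scans[i + 1])
        n_correct <- n_correct + 1L
    }
  }
  list(link_precision = if (n_est) n_correct / n_est else 1.0,
       link_recall = n_correct / n_truth_links,
       track_purity = if (length(purities)) mean(purities) else 1.0,
       n_links_est = n_est, n_links_truth = n_truth_links,
       n_links_correct = n_correct)
}
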