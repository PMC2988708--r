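# Processing manager: configurable source -> stats -> blips -> tracks -> sinks
# pipeline with named hooks, batch mode and structured logging. Replaces an
# interactive media-player loop with headless run-to-completion.

HOOK_NAMES <- c("SCAN_META", "SCAN_DATA", "POST_STATS", "POST_HOT",
                "POST_PATCHES", "POST_BLIPS", "POST_TRACK_STEP",
                "TRACK_COMPLETE", "SCAN_DONE")

#' Hook registry
#'
#' Named check-points between pipeline stages at which user functions can
#' inspect or replace the intermediate payload. Functions registered under one
#' hook run in registration order; each receives the payload and returns a
#' replacement (which must preserve the payload's type), and subsequent stages
#' consume the modified payload.
#'
#' @return an empty `hook_registry`.
#' @export
hook_registry <- function() {
  structure(list(hooks = stats::setNames(vector("list", length(HOOK_NAMES)),
                                         HOOK_NAMES)),
            class = "hook_registry")
}

#' @rdname hook_registry
#' @param reg a `hook_registry`.
#' @param name one of SCAN_META, SCAN_DATA, POST_STATS, POST_HOT,
#'   POST_PATCHES, POST_BLIPS, POST_TRACK_STEP, TRACK_COMPLETE, SCAN_DONE.
#' @param fn `function(payload, ...) -> payload`.
#' @export
register_hook <- function(reg, name, fn) {
  if (!name %in% HOOK_NAMES) stop("unknown hook name: ", name)
  reg$hooks[[name]] <- c(reg$hooks[[name]], fn)
  reg
}

#' @rdname hook_registry
#' @param payload the stage payload.
#' @param ... extra arguments passed to the hook functions.
#' @param strict if FALSE (default), a hook that throws leaves the payload
#'   unchanged and a warning is logged; if TRUE the error propagates.
#' @export
fire_hook <- function(reg, name, payload, ..., strict = FALSE) {
  if (!name %in% HOOK_NAMES) stop("unknown hook name: ", name)
  for (fn in reg$hooks[[name]]) {
    if (strict) payload <- fn(payload, ...)
    else {
      res <- tryCatch(fn(payload, ...), error = function(e) {
        warning("hook ", name, " failed (payload unchanged): ",
                conditionMessage(e))
        payload
      })
      payload <- res
    }
  }
  payload
}

plog <- function(level, threshold, ...) {
  levels <- c(DEBUG = 1, INFO = 2, WARN = 3)
  if (levels[[level]] < levels[[threshold]]) return(invisible())
  message(format(Sys.time(), "%Y-%m-%dT%H:%M:%OS3"), " [", level, "] ", ...)
}

#' Pipeline configuration
#'
#' @param source the scan source: a [scene_config()] (simulated), or
#'   `list(raw = path)` / `list(blipmovie = path)` for archives written by
#'   this package.
#' @param profile a [digitizer_profile()] used to validate incoming scans.
#' @param extraction an [extraction_params()].
#' @param tracker `"none"`, `"nn"` or `"mfc"`.
#' @param tracker_params a [tracker_params()].
#' @param sinks named list of output paths; recognized names: `blipmovie`,
#'   `raw`, `blip_csv`, `track_csv`, `ppi_dir` (a directory of per-scan PGM
#'   images). At least one sink is required.
#' @param npix PPI raster side length for the `ppi_dir` sink.
#' @param seed run seed (also used for the scene when the source is one and
#'   the scene has no seed of its own).
#' @param max_scans optional cap on the number of scans processed.
#' @param log_level `"DEBUG"`, `"INFO"` or `"WARN"`.
#' @param strict_hooks abort on hook failure instead of logging and
#'   continuing.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(source, profile = digitizer_profile(),
                            extraction = extraction_params(),
                            tracker = c("none", "nn", "mfc"),
                            tracker_params = aeroscan::tracker_params(),
                            sinks = list(), npix = 256L, seed = 1L,
                            max_scans = NULL, log_level = "WARN",
                            strict_hooks = FALSE) {
  tracker <- match.arg(tracker)
  if (!length(sinks)) stop("at least one sink is required")
  known <- c("blipmovie", "raw", "blip_csv", "track_csv", "ppi_dir")
  bad <- setdiff(names(sinks), known)
  if (length(bad)) stop("unknown sink(s): ", paste(bad, collapse = ", "))
  structure(list(source = source, profile = profile, extraction = extraction,
                 tracker = tracker, tracker_params = tracker_params,
                 sinks = sinks, npix = as.integer(npix),
                 seed = as.integer(seed), max_scans = max_scans,
                 log_level = log_level, strict_hooks = strict_hooks),
            class = "pipeline_config")
}

# resolve the configured source into a list of scans (+ optional blips/truth)
resolve_source <- function(config) {
  src <- config$source
  if (inherits(src, "scene_config")) {
    sim <- simulate_scene(src)
    return(list(scans = sim$scans, truth = sim$truth, blips = NULL))
  }
  if (is.list(src) && !is.null(src$raw))
    return(list(scans = read_raw(src$raw)$scans, truth = NULL, blips = NULL))
  if (is.list(src) && !is.null(src$blipmovie)) {
    bm <- read_blipmovie(src$blipmovie)
    return(list(scans = NULL, truth = NULL,
                metas = lapply(bm$records, function(r) list_to_meta(r$meta)),
                blips = lapply(bm$records, record_to_blips)))
  }
  stop("invalid source: expected a scene_config, list(raw=path) or ",
       "list(blipmovie=path)")
}

#' Run the processing pipeline
#'
#' Executes the learn phase (the first `learn_scans` scans initialize the
#' background and emit no blips), then per scan: blip extraction, optional
#' tracking and every configured sink, firing hooks in stage order
#' (SCAN_META, SCAN_DATA, POST_STATS, POST_HOT, POST_PATCHES, POST_BLIPS,
#' POST_TRACK_STEP, TRACK_COMPLETE, SCAN_DONE). Deterministic given the
#' configuration and seed. A blipmovie source skips the stats/extraction
#' stages and feeds its stored blips straight to the tracker and sinks.
#'
#' @param config a [pipeline_config()].
#' @param hooks a [hook_registry()] (optional).
#' @return run summary: list with `scans_processed`, `blips_found`,
#'   `tracks_completed`, `sink_paths`, `per_scan` (data.frame of hot/patch/
#'   blip counts), and `tracker_state` when tracking was enabled.
#' @export
run_pipeline <- function(config, hooks = hook_registry()) {
  stopifnot(inherits(config, "pipeline_config"))
  lvl <- config$log_level
  strict <- config$strict_hooks
  src <- resolve_source(config)
  ex <- config$extraction

  from_blipmovie <- is.null(src$scans)
  n_avail <- if (from_blipmovie) length(src$blips) else length(src$scans)
  n_proc <- if (is.null(config$max_scans)) n_avail else
    min(n_avail, config$max_scans)
  plog("INFO", lvl, "source provides ", n_avail, " scans; processing ",
       n_proc)

  state <- if (config$tracker != "none")
    new_tracker(config$tracker, config$tracker_params) else NULL
  bg <- NULL
  all_records <- list()
  raw_scans <- list()
  blip_rows <- list()
  per_scan <- list()
  n_blips_total <- 0L
  completed <- integer(0)

  learn_buf <- list()
  learn_n <- if (from_blipmovie) 0L else ex$learn_scans

  for (s in seq_len(n_proc)) {
    scan_index <- s - 1L
    if (from_blipmovie) {
      meta <- src$metas[[s]]
      blips <- src$blips[[s]]
      scan <- NULL
    } else {
      scan <- src$scans[[s]]
      viol <- validate_scan(scan, config$profile)
      if (length(viol))
        plog("WARN", lvl, "scan ", scan_index, ": ",
             paste(vapply(viol, `[[`, character(1), "message"),
                   collapse = "; "))
      meta <- fire_hook(hooks, "SCAN_META", scan$meta, strict = strict)
      scan$meta <- meta
      scan <- fire_hook(hooks, "SCAN_DATA", scan, strict = strict)
      if (s <= learn_n) {
        learn_buf[[s]] <- scan
        if (s == learn_n) {
          bg <- learn_background(learn_buf, ex$grid, ex$estimator)
          bg <- fire_hook(hooks, "POST_STATS", bg, strict = strict)
          plog("INFO", lvl, "background learned from ", learn_n, " scans")
        }
        per_scan[[s]] <- data.frame(scan = scan_index, hot = NA_integer_,
                                    patches = NA_integer_, blips = 0L,
                                    phase = "learn")
        next
      }
      mask <- find_hot(scan, bg, ex$z_thresh)
      mask <- apply_sector_rules(NULL, mask, ex$sectors, scan$meta)$mask
      mask <- fire_hook(hooks, "POST_HOT", mask, strict = strict)
      patches <- group_patches(mask)
      patches <- fire_hook(hooks, "POST_PATCHES", patches, strict = strict)
      blips <- lapply(patches, blip_properties, scan = scan)
      blips <- filter_blips(blips, ex$filters)
      blips <- apply_sector_rules(blips, NULL, ex$sectors, scan$meta)$blips
      if (length(blips)) {
        az <- vapply(blips, function(b) (atan2(b$x, b$y) * 180 / pi) %% 360,
                     numeric(1))
        ts <- vapply(blips, `[[`, numeric(1), "t")
        blips <- blips[order(ts, az)]
      }
      if (ex$update_enabled)
        bg <- update_background(bg, scan, ex$alpha,
                                exclude_hot = ex$exclude_hot, mask = mask)
    }
    blips <- fire_hook(hooks, "POST_BLIPS", blips, strict = strict)
    n_blips_total <- n_blips_total + length(blips)

    track_ids <- rep(NA_integer_, length(blips))
    if (!is.null(state)) {
      stepf <- if (config$tracker == "nn") step_nn else step_mfc
      state <- stepf(state, blips, scan_index)
      state <- fire_hook(hooks, "POST_TRACK_STEP", state, strict = strict)
      for (id in state$completed_this_step) {
        completed <- c(completed, id)
        tr <- state$tracks[[which(vapply(state$tracks, `[[`, integer(1),
                                         "id") == id)]]
        fire_hook(hooks, "TRACK_COMPLETE", tr, strict = strict)
      }
    }
    if (!is.null(config$sinks$blipmovie))
      all_records[[length(all_records) + 1]] <- blipmovie_record(meta, blips)
    if (!is.null(config$sinks$raw) && !from_blipmovie)
      raw_scans[[length(raw_scans) + 1]] <- scan
    if (!is.null(config$sinks$blip_csv))
      blip_rows[[length(blip_rows) + 1]] <- blips
    if (!is.null(config$sinks$ppi_dir) && !from_blipmovie) {
      dir.create(config$sinks$ppi_dir, showWarnings = FALSE, recursive = TRUE)
      write_pgm(scan_to_ppi(scan, config$npix),
                file.path(config$sinks$ppi_dir,
                          sprintf("scan_%04d.pgm", scan_index)))
    }
    per_scan[[s]] <- data.frame(
      scan = scan_index,
      hot = if (from_blipmovie) NA_integer_ else sum(mask),
      patches = if (from_blipmovie) NA_integer_ else length(patches),
      blips = length(blips), phase = "process")
    plog("INFO", lvl, "scan ", scan_index, ": ",
         if (from_blipmovie) "" else paste0(sum(mask), " hot, ",
                                            length(patches), " patches, "),
         length(blips), " blips")
    fire_hook(hooks, "SCAN_DONE", list(scan_index = scan_index,
                                       n_blips = length(blips)),
              strict = strict)
  }

  if (!is.null(state)) {
    for (ti in seq_along(state$tracks)) {
      if (state$tracks[[ti]]$state == "active") {
        state$tracks[[ti]]$state <- "complete"
        completed <- c(completed, state$tracks[[ti]]$id)
        fire_hook(hooks, "TRACK_COMPLETE", state$tracks[[ti]],
                  strict = strict)
      }
    }
  }

  sink_paths <- character(0)
  if (!is.null(config$sinks$blipmovie)) {
    write_blipmovie(all_records, config$sinks$blipmovie)
    sink_paths <- c(sink_paths, blipmovie = config$sinks$blipmovie)
  }
  if (!is.null(config$sinks$raw) && length(raw_scans)) {
    write_raw(raw_scans, config$sinks$raw)
    sink_paths <- c(sink_paths, raw = config$sinks$raw)
  }
  if (!is.null(config$sinks$blip_csv)) {
    if (!is.null(state)) {
      # tracked export: blips appear with their track ids
      export_blips(state, config$sinks$blip_csv)
    } else {
      export_blips(do.call(c, c(blip_rows, list(list()))),
                   config$sinks$blip_csv)
    }
    sink_paths <- c(sink_paths, blip_csv = config$sinks$blip_csv)
  }
  if (!is.null(config$sinks$track_csv) && !is.null(state)) {
    export_tracks(state, config$sinks$track_csv)
    sink_paths <- c(sink_paths, track_csv = config$sinks$track_csv)
  }
  if (!is.null(config$sinks$ppi_dir))
    sink_paths <- c(sink_paths, ppi_dir = config$sinks$ppi_dir)

  list(scans_processed = n_proc,
       blips_found = n_blips_total,
       tracks_completed = length(unique(completed)),
       sink_paths = sink_paths,
       per_scan = do.call(rbind, per_scan),
       tracker_state = state,
       truth = src$truth)
}

#' Parse a pipeline configuration file (JSON or YAML)
#'
#' The file holds the same fields as [pipeline_config()]; the scene source is
#' given under `source$scene` with plain-list target/clutter/meta fields.
#'
#' @param path configuration file (`.json`, `.yml`/`.yaml`).
#' @return a [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else jsonlite::fromJSON(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  src <- raw$source
  if (!is.null(src$scene)) {
    sc <- src$scene
    meta <- do.call(scan_meta, sc$meta[names(sc$meta) != "antenna"])
    if (!is.null(sc$meta$antenna))
      meta$antenna <- do.call(antenna_config, sc$meta$antenna)
    targets <- lapply(sc$targets, function(tg) do.call(target_spec, tg))
    clutter <- if (!is.null(sc$clutter)) do.call(clutter_spec, sc$clutter)
      else clutter_spec()
    source <- scene_config(meta, sc$n_scans, targets, clutter,
                           seed = if (!is.null(sc$seed)) sc$seed else
                             if (!is.null(raw$seed)) raw$seed else 1L)
  } else source <- src
  ex_args <- raw$extraction
  if (!is.null(ex_args$filters))
    ex_args$filters <- do.call(blip_filters, ex_args$filters)
  if (!is.null(ex_args$grid)) ex_args$grid <- do.call(stats_grid, ex_args$grid)
  extraction <- if (length(ex_args)) do.call(extraction_params, ex_args)
    else extraction_params()
  tp <- if (!is.null(raw$tracker_params))
    do.call(tracker_params, raw$tracker_params) else tracker_params()
  pipeline_config(
    source = source, extraction = extraction,
    tracker = if (!is.null(raw$tracker)) raw$tracker else "none",
    tracker_params = tp,
    sinks = raw$sinks,
    npix = if (!is.null(raw$npix)) raw$npix else 256L,
    seed = if (!is.null(raw$seed)) raw$seed else 1L,
    max_scans = raw$max_scans,
    log_level = if (!is.null(raw$log_level)) raw$log_level else "WARN",
    strict_hooks = isTRUE(raw$strict_hooks))
}

#' Run several pipeline configurations in sequence
#'
#' Jobs run with isolated state; one failure does not stop later jobs.
#'
#' @param config_paths character vector of configuration file paths.
#' @return list of per-job results: each either a run summary or a
#'   `list(error = message)`. The attribute `exit_status` is 0 when every job
#'   succeeded, 1 otherwise.
#' @export
run_batch <- function(config_paths) {
  out <- lapply(config_paths, function(p) {
    tryCatch(run_pipeline(read_pipeline_config(p)),
             error = function(e) list(error = conditionMessage(e), path = p))
  })
  failed <- any(vapply(out, function(x) !is.null(x$error), logical(1)))
  attr(out, "exit_status") <- if (failed) 1L else 0L
  out
}
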