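# Compressed self-describing text archives (raw scans and blipmovies) with
# forward/backward compatibility, plus delimited-text exports of blips and
# tracks.
#
# Containers are gzip (DEFLATE) streams of newline-delimited records in a
# canonical JSON serialization: object keys lexicographically sorted, no
# insignificant whitespace, shortest round-trip number form. Line 1 is the
# archive header; unknown keys at any level survive a read/write cycle.

BLIPMOVIE_VERSION <- 1L
RAWSCAN_VERSION <- 1L

# recursively sort names of named lists so serialization is canonical
sort_keys <- function(x) {
  if (is.list(x) && !is.null(names(x)) && length(x))
    x <- lapply(x[order(names(x))], sort_keys)
  else if (is.list(x))
    x <- lapply(x, sort_keys)
  x
}

canonical_json <- function(x) {
  as.character(jsonlite::toJSON(sort_keys(x), auto_unbox = TRUE, digits = NA,
                                null = "null", na = "null"))
}

# scan_meta -> plain named list (antenna flattened as a sub-object);
# unknown keys carried in attr(meta, "extra") are appended
meta_to_list <- function(meta) {
  m <- unclass(meta)
  extra <- attr(m, "extra")
  attr(m, "extra") <- NULL
  m$antenna <- unclass(m$antenna)
  if (!is.null(extra)) m <- c(m, extra)
  m
}

list_to_meta <- function(l) {
  ant <- do.call(antenna_config, l$antenna[names(l$antenna) %in%
                   names(formals(antenna_config))])
  known <- names(formals(scan_meta))
  args <- l[names(l) %in% setdiff(known, "antenna")]
  args$lat <- if (is.null(args$lat)) NA_real_ else args$lat
  args$lon <- if (is.null(args$lon)) NA_real_ else args$lon
  args$antenna <- ant
  meta <- do.call(scan_meta, args)
  extra <- l[!(names(l) %in% known)]
  if (length(extra)) attr(meta, "extra") <- extra
  meta
}

#' Build a blipmovie record from a scan's metadata and blips
#'
#' @param meta a [scan_meta()] (or plain named list of metadata).
#' @param blips list of [blip_properties()] objects.
#' @param extra optional named list of additional metadata to preserve.
#' @return a plain-list record suitable for [write_blipmovie()].
#' @export
blipmovie_record <- function(meta, blips = list(), extra = list()) {
  ml <- if (inherits(meta, "scan_meta")) meta_to_list(meta) else meta
  ml <- c(ml, extra)
  bl <- lapply(blips, function(b) {
    props <- unclass(b)
    props$cells <- NULL
    list(cells = unname(apply(b$cells, 1, function(r) as.numeric(r),
                              simplify = FALSE)),
         props = props)
  })
  list(meta = ml, blips = bl)
}

#' Write / read a blipmovie archive
#'
#' A blipmovie stores, per scan, the full scan metadata and the retained blips
#' (raw cell triples plus summary properties). Unknown keys anywhere in a
#' record are preserved across read/write cycles, so future fields survive.
#'
#' @param records list of records from [blipmovie_record()] (or read back).
#' @param path file path (gzip-compressed).
#' @param header_extra named list of extra header metadata to store.
#' @return `write_blipmovie`: `path`, invisibly. `read_blipmovie`: list with
#'   `header` and `records`.
#' @export
write_blipmovie <- function(records, path, header_extra = list()) {
  header <- c(list(format = "blipmovie", version = BLIPMOVIE_VERSION),
              header_extra)
  con <- gzfile(path, "wb")
  on.exit(close(con))
  writeLines(c(canonical_json(header),
               vapply(records, canonical_json, character(1))), con)
  invisible(path)
}

parse_archive <- function(path, expect_format) {
  con <- gzfile(path, "rb")
  on.exit(close(con))
  lines <- tryCatch(readLines(con), error = function(e)
    stop("truncated or unreadable archive: ", conditionMessage(e)))
  if (!length(lines)) stop("truncated archive: no header line")
  header <- tryCatch(jsonlite::fromJSON(lines[1], simplifyVector = FALSE),
                     error = function(e) stop("malformed line 1: ",
                                              conditionMessage(e)))
  if (!identical(header$format, expect_format))
    stop("not a ", expect_format, " archive (format: ",
         if (is.null(header$format)) "<missing>" else header$format, ")")
  supported <- if (expect_format == "blipmovie") BLIPMOVIE_VERSION else
    RAWSCAN_VERSION
  if (header$version > supported)
    warning("archive version ", header$version, " is newer than supported (",
            supported, "); reading best-effort")
  body <- lines[-1]
  records <- vector("list", length(body))
  for (i in seq_along(body)) {
    records[[i]] <- tryCatch(
      jsonlite::fromJSON(body[i], simplifyVector = FALSE),
      error = function(e) stop("malformed line ", i + 1, ": ",
                               conditionMessage(e)))
  }
  list(header = header, records = records)
}

#' @rdname write_blipmovie
#' @export
read_blipmovie <- function(path) {
  parse_archive(path, "blipmovie")
}

# reconstruct blip objects from a parsed blipmovie record
record_to_blips <- function(record) {
  lapply(record$blips, function(b) {
    cells <- do.call(rbind, lapply(b$cells, as.numeric))
    colnames(cells) <- c("row", "col", "value")
    props <- b$props
    props$cells <- cells
    class(props) <- "blip"
    props
  })
}

encode_dense <- function(data) {
  if (max(data) > 65535) stop("sample value exceeds 16-bit storage")
  # little-endian unsigned 16-bit, row-major
  v <- as.integer(t(data))
  bytes <- as.raw(c(rbind(v %% 256L, v %/% 256L)))
  jsonlite::base64_enc(bytes)
}

decode_dense <- function(b64, nrow, ncol) {
  bytes <- tryCatch(jsonlite::base64_dec(gsub("\\s", "", b64)),
                    error = function(e) stop("malformed base64: ",
                                             conditionMessage(e)))
  n <- length(bytes)
  if (n != 2 * nrow * ncol) stop("malformed base64: wrong payload size")
  v <- as.integer(bytes[seq(1, n, 2)]) + 256L * as.integer(bytes[seq(2, n, 2)])
  matrix(v, nrow, ncol, byrow = TRUE)
}

#' Write / read a raw scan archive
#'
#' Dense mode stores each scan's matrix as base64 of little-endian unsigned
#' 16-bit values, row-major. With `threshold > 0`, sparse mode stores only the
#' (row, col, value) triples with `value >= threshold` and the reader fills
#' zeros elsewhere. With a `sector` restriction (`c(az_lo, az_hi)` degrees),
#' only the pulse columns inside the sector are stored, together with their
#' 0-based column indices so azimuth provenance is retained; the reader
#' reconstructs a full-width matrix with zero columns elsewhere.
#'
#' @param scans list of [radar_scan()] objects.
#' @param path file path (gzip-compressed).
#' @param threshold noise threshold; 0 (default) selects dense storage.
#' @param sector optional `c(az_lo, az_hi)` azimuth restriction.
#' @param header_extra named list of extra header metadata.
#' @return `write_raw`: `path`, invisibly. `read_raw`: list with `header` and
#'   `scans` (list of [radar_scan()]).
#' @export
write_raw <- function(scans, path, threshold = 0, sector = NULL,
                      header_extra = list()) {
  header <- c(list(format = "rawscan", version = RAWSCAN_VERSION),
              header_extra)
  recs <- lapply(scans, function(s) {
    meta <- meta_to_list(s$meta)
    data <- s$data
    cols_kept <- NULL
    if (!is.null(sector)) {
      az <- azimuth_of_pulse(seq_len(s$meta$n_pulses) - 1, s$meta)
      keep <- az_in_interval(az, sector[1], sector[2])
      cols_kept <- which(keep) - 1L
      data <- data[, keep, drop = FALSE]
    }
    if (threshold > 0) {
      hit <- which(data >= threshold)
      rows <- ((hit - 1L) %% nrow(data))
      cols <- ((hit - 1L) %/% nrow(data))
      if (!is.null(cols_kept)) cols <- cols_kept[cols + 1L] else cols <- cols
      rec <- list(meta = meta, encoding = "sparse", threshold = threshold,
                  rows = as.integer(rows), cols = as.integer(cols),
                  values = as.integer(data[hit]))
    } else {
      rec <- list(meta = meta, encoding = "dense", data = encode_dense(data),
                  stored_cols = ncol(data))
    }
    if (!is.null(cols_kept)) rec$cols_kept <- as.integer(cols_kept)
    rec
  })
  con <- gzfile(path, "wb")
  on.exit(close(con))
  writeLines(c(canonical_json(header),
               vapply(recs, canonical_json, character(1))), con)
  invisible(path)
}

#' @rdname write_raw
#' @export
read_raw <- function(path) {
  parsed <- parse_archive(path, "rawscan")
  scans <- lapply(parsed$records, function(rec) {
    meta <- list_to_meta(rec$meta)
    data <- matrix(0L, meta$n_samples, meta$n_pulses)
    if (identical(rec$encoding, "dense")) {
      ncol_stored <- if (!is.null(rec$stored_cols)) rec$stored_cols else
        meta$n_pulses
      stored <- decode_dense(rec$data, meta$n_samples, ncol_stored)
      if (!is.null(rec$cols_kept))
        data[, unlist(rec$cols_kept) + 1L] <- stored
      else data <- stored
    } else if (identical(rec$encoding, "sparse")) {
      if (length(rec$rows))
        data[cbind(unlist(rec$rows) + 1L, unlist(rec$cols) + 1L)] <-
          unlist(rec$values)
    } else stop("unknown encoding: ", rec$encoding)
    radar_scan(data, meta)
  })
  list(header = parsed$header, scans = scans)
}

#' Convert a blip list to a data frame
#'
#' @param blips list of [blip_properties()] objects.
#' @param track_ids optional integer vector (NA = untracked), recycled.
#' @return data.frame with the export columns.
#' @export
blips_table <- function(blips, track_ids = NULL) {
  if (is.null(track_ids)) track_ids <- rep(NA_integer_, length(blips))
  get1 <- function(f) vapply(blips, `[[`, numeric(1), f)
  data.frame(ts = get1("t"), x_m = get1("x"), y_m = get1("y"),
             z_m = get1("z"), n_samples = get1("n_samples"),
             area_m2 = get1("area_m2"),
             perimeter_cells = get1("perimeter_cells"),
             int_mean = get1("int_mean"), int_max = get1("int_max"),
             angular_span_deg = get1("angular_span_deg"),
             radial_span_m = get1("radial_span_m"),
             track_id = track_ids)
}

#' Export blips to delimited text (RFC 4180 CSV)
#'
#' Columns, in order: ts, x_m, y_m, z_m, n_samples, area_m2, perimeter_cells,
#' int_mean, int_max, angular_span_deg, radial_span_m, track_id. The header
#' row is always written; `track_id` is empty for untracked blips. When a
#' tracker state is supplied, track ids are dense positive integers in order
#' of track creation.
#'
#' @param blips list of blips, or a `tracker_state` (exports every blip of
#'   every track).
#' @param path output path.
#' @param track_ids optional integer vector parallel to `blips`.
#' @return `path`, invisibly.
#' @export
export_blips <- function(blips, path, track_ids = NULL) {
  if (inherits(blips, "tracker_state")) {
    st <- blips
    blips <- list(); track_ids <- integer(0)
    for (tr in st$tracks) {
      blips <- c(blips, tr$blips)
      track_ids <- c(track_ids, rep(tr$id, length(tr$blips)))
    }
  }
  df <- blips_table(blips, track_ids)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

track_summary_row <- function(tr) {
  n <- length(tr$blips)
  xyz <- t(vapply(tr$blips, blip_xyz, numeric(3)))
  ts <- vapply(tr$blips, `[[`, numeric(1), "t")
  seg <- sqrt(rowSums((xyz[-1, , drop = FALSE] -
                         xyz[-n, , drop = FALSE])^2))
  dt <- diff(ts)
  path_len <- sum(seg)
  net <- sqrt(sum((xyz[n, ] - xyz[1, ])^2))
  hd <- (atan2(xyz[n, 1] - xyz[1, 1], xyz[n, 2] - xyz[1, 2]) * 180 / pi) %% 360
  data.frame(id = tr$id, n_blips = n, t_start = ts[1], t_end = ts[n],
             mean_speed_mps = mean(seg / dt),
             net_heading_deg = hd,
             straightness = if (path_len > 0) net / path_len else 1)
}

#' Summarize tracks as a data frame
#'
#' One row per track: id, n_blips, t_start, t_end, mean_speed_mps (mean of
#' consecutive-pair speeds), net_heading_deg (bearing from first to last
#' blip), straightness (net displacement / path length; 0 for an out-and-back
#' track).
#'
#' @param state a `tracker_state` or list of tracks.
#' @param min_blips drop tracks with fewer blips (default 2; speed needs a
#'   pair).
#' @return data.frame, one row per track, in order of track creation.
#' @export
tracks_table <- function(state, min_blips = 2L) {
  tracks <- if (inherits(state, "tracker_state")) state$tracks else state
  tracks <- tracks[vapply(tracks, function(tr) length(tr$blips) >= min_blips,
                          logical(1))]
  if (!length(tracks))
    return(data.frame(id = integer(), n_blips = integer(), t_start = numeric(),
                      t_end = numeric(), mean_speed_mps = numeric(),
                      net_heading_deg = numeric(), straightness = numeric()))
  do.call(rbind, lapply(tracks, track_summary_row))
}

#' Export track summaries to CSV
#'
#' @inheritParams tracks_table
#' @param path output path.
#' @return `path`, invisibly.
#' @export
export_tracks <- function(state, path, min_blips = 2L) {
  utils::write.csv(tracks_table(state, min_blips), path, row.names = FALSE,
                   na = "")
  invisible(path)
}
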