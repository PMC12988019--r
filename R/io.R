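# Track and metadata I/O. CSV tracks are `time,lat,lon` with a header
# (time either numeric seconds or ISO-8601 timestamps, auto-detected);
# GPX 1.1 <trk> is the alternative interchange format. Times are always
# rebased so the first retained fix is t = 0; the original wall-clock
# start, when present, is kept as the `start_offset_s` attribute.

.parse_time_column <- function(x) {
  num <- suppressWarnings(as.numeric(x))
  if (!all(is.na(num))) return(list(t = num, t0 = NA_real_))
  ts <- as.POSIXct(x, tz = "UTC",
                   tryFormats = c("%Y-%m-%dT%H:%M:%OSZ", "%Y-%m-%dT%H:%M:%OS",
                                  "%Y-%m-%d %H:%M:%OS"))
  list(t = as.numeric(ts) - as.numeric(ts[!is.na(ts)][1]),
       t0 = as.numeric(ts[!is.na(ts)][1]))
}

#' Read a GPS track
#'
#' Reads a homing track from CSV (columns `time,lat,lon`, header required)
#' or GPX 1.1. Rows with unparseable coordinates are dropped (with a
#' message); fewer than two valid fixes, missing columns, or non-monotone
#' timestamps are errors — malformed input never yields a silent partial
#' result.
#'
#' @param path file path.
#' @param format `"csv"` or `"gpx"`; default guessed from the extension.
#' @param bird_id,release_id identifiers attached to the trajectory.
#' @return a [trajectory()].
#' @export
read_track <- function(path, format = c("auto", "csv", "gpx"),
                       bird_id = NA_character_, release_id = NA_character_) {
  format <- match.arg(format)
  if (!file.exists(path))
    rm_abort("rm_io_error", "no such file: %s", path)
  if (format == "auto")
    format <- if (grepl("\\.gpx$", path, ignore.case = TRUE)) "gpx" else "csv"
  if (format == "csv") .read_track_csv(path, bird_id, release_id)
  else .read_track_gpx(path, bird_id, release_id)
}

.read_track_csv <- function(path, bird_id, release_id) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time", "lat", "lon")
  if (!all(need %in% names(df)))
    rm_abort("rm_format_error", "track CSV %s lacks column(s): %s", path,
             paste(setdiff(need, names(df)), collapse = ", "))
  tm <- .parse_time_column(df$time)
  lat <- suppressWarnings(as.numeric(df$lat))
  lon <- suppressWarnings(as.numeric(df$lon))
  ok <- is.finite(tm$t) & is.finite(lat) & is.finite(lon) &
    lat >= -90 & lat <= 90 & lon >= -180 & lon <= 180
  if (any(!ok))
    message(sprintf("read_track: dropped %d unparseable fix(es) from %s",
                    sum(!ok), path))
  if (sum(ok) < 2)
    rm_abort("rm_degenerate_error",
             "fewer than 2 valid fixes in %s", path)
  t <- tm$t[ok]
  trajectory(t - t[1], lat[ok], lon[ok], bird_id = bird_id,
             release_id = release_id,
             start_offset_s = if (is.na(tm$t0)) t[1] else tm$t0 + t[1])
}

.GPX_EPOCH <- as.POSIXct("2024-01-01 00:00:00", tz = "UTC")

.read_track_gpx <- function(path, bird_id, release_id) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  pts <- xml2::xml_find_all(doc, ".//trk/trkseg/trkpt")
  if (length(pts) == 0)
    rm_abort("rm_format_error", "no <trkpt> track points in %s", path)
  lat <- as.numeric(xml2::xml_attr(pts, "lat"))
  lon <- as.numeric(xml2::xml_attr(pts, "lon"))
  tstr <- xml2::xml_text(xml2::xml_find_first(pts, "./time"))
  tt <- as.POSIXct(tstr, tz = "UTC",
                   tryFormats = c("%Y-%m-%dT%H:%M:%OSZ", "%Y-%m-%dT%H:%M:%OS"))
  ok <- is.finite(lat) & is.finite(lon) & !is.na(tt)
  if (sum(ok) < 2)
    rm_abort("rm_degenerate_error", "fewer than 2 valid fixes in %s", path)
  t <- as.numeric(tt[ok])
  trajectory(t - t[1], lat[ok], lon[ok], bird_id = bird_id,
             release_id = release_id, start_offset_s = t[1] - as.numeric(.GPX_EPOCH))
}

#' Write a GPS track
#'
#' Writes a trajectory as CSV or GPX 1.1, lossless to 1e-7 degrees (about
#' 1 cm) in coordinates; CSV keeps times at full double precision, GPX at
#' millisecond precision.
#'
#' @param traj a [trajectory()].
#' @param path output path.
#' @param format `"csv"` or `"gpx"`; default guessed from the extension.
#' @export
write_track <- function(traj, path, format = c("auto", "csv", "gpx")) {
  format <- match.arg(format)
  if (!is_trajectory(traj))
    rm_abort("rm_format_error", "write_track needs a trajectory object")
  if (format == "auto")
    format <- if (grepl("\\.gpx$", path, ignore.case = TRUE)) "gpx" else "csv"
  if (format == "csv") {
    df <- data.frame(time = format(traj$time, digits = 15, trim = TRUE,
                                   scientific = FALSE),
                     lat = sprintf("%.7f", traj$lat),
                     lon = sprintf("%.7f", traj$lon))
    ok <- tryCatch({
      utils::write.csv(df, path, row.names = FALSE, quote = FALSE); TRUE
    }, error = function(e) FALSE, warning = function(w) FALSE)
    if (!ok) rm_abort("rm_io_error", "cannot write %s", path)
  } else {
    t0 <- attr(traj, "start_offset_s")
    if (is.na(t0)) t0 <- 0
    abs_t <- .GPX_EPOCH + t0 + traj$time
    tstr <- strftime(abs_t, "%Y-%m-%dT%H:%M:%OS3Z", tz = "UTC")
    pts <- paste0(sprintf('      <trkpt lat="%.7f" lon="%.7f"><time>%s</time></trkpt>',
                          traj$lat, traj$lon, tstr), collapse = "\n")
    doc <- paste0(
      '<?xml version="1.0" encoding="UTF-8"?>\n',
      '<gpx version="1.1" creator="routemem" ',
      'xmlns="http://www.topografix.com/GPX/1/1">\n',
      '  <trk>\n    <name>', attr(traj, "bird_id"), '</name>\n    <trkseg>\n',
      pts, '\n    </trkseg>\n  </trk>\n</gpx>\n')
    ok <- tryCatch({ writeLines(doc, path); TRUE },
                   error = function(e) FALSE, warning = function(w) FALSE)
    if (!ok) rm_abort("rm_io_error", "cannot write %s", path)
  }
  invisible(path)
}

.META_LEVELS <- list(site = c("A", "B"),
                     treatment = c("forgetting", "extra_training"),
                     condition = c("paired", "solo"),
                     testing_time = c("baseline", "memory_testing"))

#' Read and validate the release-metadata table
#'
#' The metadata CSV binds each track to its bird, pair, site, treatment,
#' release condition and testing time; columns `release_id, bird_id,
#' pair_id, site, treatment, condition, testing_time, release_order` plus
#' an optional `release_start_s` wall-clock offset. All structural
#' invariants are checked: level labels, uniqueness of (bird, release),
#' paired releases carrying exactly two birds of the same pair, and a
#' constant pair per bird. Violations are reported with row numbers.
#'
#' @param path CSV path.
#' @return a data.frame of release records (factors for design variables).
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) rm_abort("rm_io_error", "no such file: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_metadata(df)
}

#' Validate a release-metadata data.frame
#' @param df data.frame with the release-record columns.
#' @return the validated data.frame, with design variables as factors.
#' @export
validate_metadata <- function(df) {
  need <- c("release_id", "bird_id", "pair_id", "site", "treatment",
            "condition", "testing_time", "release_order")
  if (!all(need %in% names(df)))
    rm_abort("rm_format_error", "metadata lacks column(s): %s",
             paste(setdiff(need, names(df)), collapse = ", "))
  for (f in names(.META_LEVELS)) {
    bad <- which(!df[[f]] %in% .META_LEVELS[[f]])
    if (length(bad))
      rm_abort("rm_domain_error", "unknown %s label %s at row %d",
               f, dQuote(df[[f]][bad[1]]), bad[1])
    df[[f]] <- factor(df[[f]], levels = .META_LEVELS[[f]])
  }
  key <- paste(df$bird_id, df$release_id)
  if (anyDuplicated(key))
    rm_abort("rm_consistency_error", "duplicate (bird_id, release_id) at row %d",
             which(duplicated(key))[1])
  rows_by_rid <- split(seq_len(nrow(df)), df$release_id)
  for (rid in names(rows_by_rid)) {
    rows <- rows_by_rid[[rid]]
    cond <- df$condition[rows]
    if (cond[1] == "paired" && length(rows) != 2)
      rm_abort("rm_consistency_error",
               "paired release %s has %d bird(s), expected 2 (rows %s)",
               rid, length(rows), paste(rows, collapse = ","))
    if (cond[1] == "solo" && length(rows) != 1)
      rm_abort("rm_consistency_error",
               "solo release %s has %d birds, expected 1", rid, length(rows))
    if (length(unique(df$pair_id[rows])) != 1)
      rm_abort("rm_consistency_error",
               "pair_id mismatch within release %s (rows %s)",
               rid, paste(rows, collapse = ","))
  }
  bp <- unique(df[, c("bird_id", "pair_id")])
  if (anyDuplicated(bp$bird_id))
    rm_abort("rm_consistency_error", "bird %s appears under two pair_ids",
             bp$bird_id[duplicated(bp$bird_id)][1])
  df
}

#' Pair membership lookup
#'
#' @param metadata validated metadata data.frame.
#' @return data.frame with one row per pair: `pair_id`, `bird_a`, `bird_b`.
#' @export
pair_members <- function(metadata) {
  bp <- unique(metadata[, c("pair_id", "bird_id")])
  sp <- split(bp$bird_id, bp$pair_id)
  data.frame(pair_id = names(sp),
             bird_a = vapply(sp, function(b) sort(b)[1], ""),
             bird_b = vapply(sp, function(b) sort(b)[min(2, length(b))], ""),
             row.names = NULL)
}
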