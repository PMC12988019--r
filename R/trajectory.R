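# The trajectory container: an ordered series of timestamped GPS fixes for
# one bird on one release. Plain data.frame (time, lat, lon) with identity
# attributes, in the style of movement-ecology track packages.

#' Signal a classed package error
#' @keywords internal
rm_abort <- function(class, msg, ...) {
  stop(structure(class = c(class, "routemem_error", "error", "condition"),
                 list(message = sprintf(msg, ...), call = sys.call(-1))))
}

#' Construct a trajectory
#'
#' A trajectory is an ordered set of GPS fixes for one bird on one release:
#' a data.frame with columns `time` (seconds since release start, strictly
#' increasing), `lat` and `lon` (decimal degrees WGS84), carrying `bird_id`,
#' `release_id` and an optional absolute release start offset (seconds on a
#' common experiment clock, used for joined-flight detection).
#'
#' @param time numeric vector, seconds; strictly increasing; length >= 2.
#' @param lat,lon coordinates in decimal degrees.
#' @param bird_id,release_id identifiers.
#' @param start_offset_s absolute release start on a shared clock (seconds),
#'   or `NA` if unknown.
#' @return an object of class `trajectory`.
#' @export
trajectory <- function(time, lat, lon, bird_id = NA_character_,
                       release_id = NA_character_, start_offset_s = NA_real_) {
  time <- as.numeric(time); lat <- as.numeric(lat); lon <- as.numeric(lon)
  n <- length(time)
  if (n != length(lat) || n != length(lon))
    rm_abort("rm_format_error", "time/lat/lon lengths differ")
  if (n < 2)
    rm_abort("rm_degenerate_error", "a trajectory needs at least 2 fixes")
  if (any(!is.finite(time)))
    rm_abort("rm_format_error", "non-finite timestamps")
  d <- diff(time)
  if (any(d <= 0)) {
    bad <- which(d <= 0)[1] + 1
    if (any(d == 0))
      rm_abort("rm_ordering_error",
               "duplicate timestamp at fix %d (ties are rejected, not averaged)",
               which(d == 0)[1] + 1)
    rm_abort("rm_ordering_error",
             "timestamps not strictly increasing at fix %d (input is not sorted silently)",
             bad)
  }
  .check_geopoint(lat, lon, sprintf("trajectory %s/%s", bird_id, release_id))
  .new_trajectory(time, lat, lon, bird_id, release_id, start_offset_s)
}

# Fast constructor without validation, for internal callers whose inputs
# satisfy the invariants by construction.
.new_trajectory <- function(time, lat, lon, bird_id, release_id,
                            start_offset_s) {
  structure(list(time = time, lat = lat, lon = lon),
            class = c("trajectory", "data.frame"),
            row.names = c(NA_integer_, -length(time)),
            bird_id = bird_id, release_id = release_id,
            start_offset_s = start_offset_s)
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> bird %s, release %s: %d fixes over %.0f s\n",
              attr(x, "bird_id"), attr(x, "release_id"),
              nrow(x), x$time[nrow(x)] - x$time[1]))
  invisible(x)
}

#' Test for the trajectory class
#' @param x object.
#' @export
is_trajectory <- function(x) inherits(x, "trajectory")

# Subset a trajectory by row indices, preserving identity attributes.
#' @keywords internal
traj_slice <- function(traj, idx) {
  .new_trajectory(traj$time[idx], traj$lat[idx], traj$lon[idx],
                  bird_id = attr(traj, "bird_id"),
                  release_id = attr(traj, "release_id"),
                  start_offset_s = attr(traj, "start_offset_s"))
}

#' Trajectory duration in seconds
#' @param traj a trajectory.
#' @export
traj_duration <- function(traj) traj$time[nrow(traj)] - traj$time[1]

#' Cumulative path length of a trajectory (metres, spherical)
#' @param traj a trajectory.
#' @export
traj_path_length <- function(traj) {
  n <- nrow(traj)
  sum(.hav_dist(traj$lat[-n], traj$lon[-n], traj$lat[-1], traj$lon[-1]))
}
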