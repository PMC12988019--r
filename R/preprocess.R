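# Track cleaning rules applied before any route metric is computed:
#   1. stationary-point removal with a 30 km/h speed filter,
#   2. trimming to the homing segment (final exit from 2 km of the release
#      point through first entry within 500 m of the loft),
#   3. joined-flight detection between separately released birds (30 s
#      samples, 50 m radius),
#   4. within-pair split truncation (150 m, no re-established proximity).
# All operations are order-stable: outputs are subsequences of inputs.

#' Preprocessing parameters
#'
#' Thresholds of the track-cleaning rules, in the units of the field
#' protocol: a 30 km/h stationary-point speed filter, a 2 km release
#' radius and 500 m home radius for homing-segment trimming, 30 s / 50 m
#' joined-flight checks and the 150 m split radius.
#'
#' @param speed_filter_kmh speed threshold; fixes slower than this are
#'   treated as stationary and removed.
#' @param release_radius_m trimming starts at the final exit from this
#'   radius around the release point.
#' @param home_radius_m trimming ends at the first entry within this radius
#'   of the home loft.
#' @param join_check_interval_s sampling interval for joined-flight checks.
#' @param join_radius_m proximity radius flagging joined flight.
#' @param join_time_tol_s time-matching tolerance when pairing fixes across
#'   tracks (half the check interval by default).
#' @param split_radius_m separation beyond which a pair is considered split
#'   if proximity is never re-established.
#' @param split_fill_gap_s maximum gap forward-filled when aligning paired
#'   tracks on a common 1 s grid.
#' @return a list of class `preprocess_params`.
#' @export
preprocess_params <- function(speed_filter_kmh = 30, release_radius_m = 2000,
                              home_radius_m = 500, join_check_interval_s = 30,
                              join_radius_m = 50, join_time_tol_s = 15,
                              split_radius_m = 150, split_fill_gap_s = 5) {
  p <- list(speed_filter_kmh = speed_filter_kmh,
            release_radius_m = release_radius_m, home_radius_m = home_radius_m,
            join_check_interval_s = join_check_interval_s,
            join_radius_m = join_radius_m, join_time_tol_s = join_time_tol_s,
            split_radius_m = split_radius_m, split_fill_gap_s = split_fill_gap_s)
  if (any(unlist(p) <= 0))
    rm_abort("rm_config_error", "preprocessing parameters must be positive")
  if (join_radius_m >= split_radius_m)
    rm_abort("rm_config_error", "join_radius_m must be < split_radius_m")
  class(p) <- "preprocess_params"
  p
}

#' Per-fix ground speeds
#'
#' Speed at fix i is the spherical distance from fix i-1 divided by the
#' time difference, in km/h; the first fix is assigned the speed of the
#' second, so the result has one value per fix.
#'
#' @param traj a [trajectory()].
#' @return numeric vector of speeds (km/h), one per fix.
#' @export
point_speeds <- function(traj) {
  n <- nrow(traj)
  d <- .hav_dist(traj$lat[-n], traj$lon[-n], traj$lat[-1], traj$lon[-1])
  v <- d / diff(traj$time) * 3.6
  c(v[1], v)
}

#' Remove stationary fixes with a speed filter
#'
#' Drops every fix whose speed — computed once, on the input track — is
#' below the threshold. Re-running on its own output (with speeds
#' recomputed) is deliberately not done; thresholding the original speed
#' series once keeps the rule deterministic and idempotent.
#'
#' @param traj a [trajectory()].
#' @param params a [preprocess_params()].
#' @return the filtered trajectory.
#' @export
filter_stationary <- function(traj, params = preprocess_params()) {
  keep <- point_speeds(traj) >= params$speed_filter_kmh
  if (sum(keep) < 2)
    rm_abort("rm_degenerate_error",
             "speed filter left %d fix(es) on %s/%s", sum(keep),
             attr(traj, "bird_id"), attr(traj, "release_id"))
  traj_slice(traj, which(keep))
}

#' Trim a track to its homing segment
#'
#' Keeps the section between the bird's final departure from the release
#' radius (the last fix within `release_radius_m` of the release point,
#' after which it never returns inside) and its first subsequent entry
#' within `home_radius_m` of the loft; both boundary-crossing fixes are
#' included.
#'
#' @param traj a [trajectory()].
#' @param release,home numeric `c(lat, lon)` of the release point and loft.
#' @param params a [preprocess_params()].
#' @return the trimmed trajectory.
#' @export
trim_homing_segment <- function(traj, release, home,
                                params = preprocess_params()) {
  d_rel <- .hav_dist(traj$lat, traj$lon, release[1], release[2])
  inside <- which(d_rel <= params$release_radius_m)
  if (length(inside) == 0)
    rm_abort("rm_nondeparture_error",
             "track %s/%s never within %g m of the release point",
             attr(traj, "bird_id"), attr(traj, "release_id"),
             params$release_radius_m)
  i_start <- max(inside)          # final fix inside: departure is final by construction
  if (i_start == nrow(traj))
    rm_abort("rm_nondeparture_error",
             "track %s/%s never leaves %g m of the release point",
             attr(traj, "bird_id"), attr(traj, "release_id"),
             params$release_radius_m)
  d_home <- .hav_dist(traj$lat, traj$lon, home[1], home[2])
  after <- which(d_home <= params$home_radius_m & seq_len(nrow(traj)) > i_start)
  if (length(after) == 0)
    rm_abort("rm_nonhoming_error",
             "track %s/%s never enters %g m of the home loft",
             attr(traj, "bird_id"), attr(traj, "release_id"),
             params$home_radius_m)
  traj_slice(traj, i_start:min(after))
}

#' Detect joined flight between separately released birds
#'
#' Samples each track every `join_check_interval_s` seconds (on its own
#' clock) and flags any sample whose nearest fix in absolute time (within
#' `join_time_tol_s`) on a track from a *different* release lies within
#' `join_radius_m`. Tracks must carry absolute release offsets
#' (`start_offset_s`) on a common clock. Flagging is symmetric in its
#' exclusion outcome: if (A,B) is flagged, (B,A) is flagged.
#'
#' @param tracks list of [trajectory()] objects.
#' @param params a [preprocess_params()].
#' @return data.frame with one row per flagged ordered pair: `release_id_a`,
#'   `bird_id_a`, `release_id_b`, `bird_id_b`, `n_flagged`, and a
#'   `flagged_times` list-column of second-offsets on track A's clock.
#' @export
detect_joining <- function(tracks, params = preprocess_params()) {
  offs <- vapply(tracks, function(tr) attr(tr, "start_offset_s"), 0)
  if (any(is.na(offs)))
    rm_abort("rm_compare_error",
             "joined-flight detection needs wall-clock offsets on every track")
  rids <- vapply(tracks, function(tr) attr(tr, "release_id"), "")
  bids <- vapply(tracks, function(tr) attr(tr, "bird_id"), "")
  out <- list()
  for (i in seq_along(tracks)) {
    for (j in seq_along(tracks)) {
      if (i == j || rids[i] == rids[j]) next
      a <- tracks[[i]]; b <- tracks[[j]]
      ta <- a$time + offs[i]; tb <- b$time + offs[j]
      # quick reject when release windows cannot overlap
      if (min(ta) > max(tb) + params$join_time_tol_s ||
          max(ta) < min(tb) - params$join_time_tol_s) next
      s_idx <- which((a$time - a$time[1]) %% params$join_check_interval_s == 0)
      flagged <- numeric(0)
      for (k in s_idx) {
        cand <- which(abs(tb - ta[k]) <= params$join_time_tol_s)
        if (length(cand) == 0) next
        dmin <- min(.hav_dist(a$lat[k], a$lon[k], b$lat[cand], b$lon[cand]))
        if (dmin <= params$join_radius_m) flagged <- c(flagged, a$time[k])
      }
      if (length(flagged))
        out[[length(out) + 1]] <-
          data.frame(release_id_a = rids[i], bird_id_a = bids[i],
                     release_id_b = rids[j], bird_id_b = bids[j],
                     n_flagged = length(flagged),
                     flagged_times = I(list(flagged)))
    }
  }
  if (length(out) == 0)
    return(data.frame(release_id_a = character(0), bird_id_a = character(0),
                      release_id_b = character(0), bird_id_b = character(0),
                      n_flagged = integer(0),
                      flagged_times = I(list())))
  do.call(rbind, out)
}

# Align a trajectory onto an integer 1 s grid, forward-filling gaps of at
# most `fill` seconds; returns lat/lon matrices with NA where unfilled.
.grid_align <- function(traj, grid, fill) {
  t_round <- round(traj$time)
  lat <- rep(NA_real_, length(grid)); lon <- lat
  m <- match(t_round, grid)
  ok <- !is.na(m)
  lat[m[ok]] <- traj$lat[ok]; lon[m[ok]] <- traj$lon[ok]
  # vectorised forward fill limited to `fill` seconds
  obs <- !is.na(lat)
  last <- cummax(ifelse(obs, seq_along(grid), 0L))
  can <- last > 0 & (grid - grid[pmax(last, 1L)]) <= fill
  lat[can] <- lat[last[can]]; lon[can] <- lon[last[can]]
  cbind(lat, lon)
}

#' Truncate a paired release at the birds' split
#'
#' Computes the inter-bird distance on a common 1 s grid (gaps forward-
#' filled up to `split_fill_gap_s`). The split time is the earliest moment
#' after which the birds are more than `split_radius_m` apart and never
#' re-establish proximity within that distance; both tracks are truncated
#' to fixes strictly before it. If the birds never split, the tracks are
#' returned whole and `split_time` is `NA`.
#'
#' @param traj_a,traj_b the two trajectories of one paired release
#'   (common time base: seconds since the shared release).
#' @param params a [preprocess_params()].
#' @return list with elements `a`, `b` (trajectories) and `split_time`.
#' @export
truncate_at_split <- function(traj_a, traj_b, params = preprocess_params()) {
  lo <- max(round(min(traj_a$time)), round(min(traj_b$time)))
  hi <- min(round(max(traj_a$time)), round(max(traj_b$time)))
  if (lo > hi)
    rm_abort("rm_compare_error", "paired tracks share no overlapping timestamps")
  grid <- lo:hi
  A <- .grid_align(traj_a, grid, params$split_fill_gap_s)
  B <- .grid_align(traj_b, grid, params$split_fill_gap_s)
  ok <- !is.na(A[, 1]) & !is.na(B[, 1])
  if (!any(ok))
    rm_abort("rm_compare_error", "paired tracks share no comparable timestamps")
  d <- rep(NA_real_, length(grid))
  d[ok] <- .hav_dist(A[ok, 1], A[ok, 2], B[ok, 1], B[ok, 2])
  near <- which(ok & d <= params$split_radius_m)
  far <- which(ok & d > params$split_radius_m)
  if (length(far) == 0)
    return(list(a = traj_a, b = traj_b, split_time = NA_real_))
  last_near <- if (length(near)) max(near) else 0
  split_idx <- min(far[far > last_near])
  split_time <- grid[split_idx]
  keep_a <- which(traj_a$time < split_time)
  keep_b <- which(traj_b$time < split_time)
  if (length(keep_a) < 2 || length(keep_b) < 2)
    rm_abort("rm_degenerate_error",
             "split at t=%g leaves a degenerate track on release %s",
             split_time, attr(traj_a, "release_id"))
  list(a = traj_slice(traj_a, keep_a), b = traj_slice(traj_b, keep_b),
       split_time = split_time)
}

#' Preprocess a full experiment
#'
#' Applies the cleaning rules in protocol order — speed filter, homing
#' trim, joined-flight detection, split truncation — to every track, and
#' returns the surviving tracks together with an exclusion ledger naming
#' the rule behind every removal or truncation.
#'
#' @param tracks named list of [trajectory()] objects (one per bird-release,
#'   names `"release_id/bird_id"`).
#' @param metadata validated metadata (see [validate_metadata()]).
#' @param sites named list mapping site label to
#'   `list(release = c(lat, lon), home = c(lat, lon))`.
#' @param params a [preprocess_params()].
#' @param check_joining logical; run the (quadratic) joined-flight scan.
#' @return list with `tracks` (surviving, cleaned), `exclusions`
#'   (data.frame: release_id, bird_id, rule, detail) and `join_flags`.
#' @export
preprocess_experiment <- function(tracks, metadata, sites,
                                  params = preprocess_params(),
                                  check_joining = TRUE) {
  excl <- list()
  note <- function(rid, bid, rule, detail)
    excl[[length(excl) + 1]] <<- data.frame(release_id = rid, bird_id = bid,
                                            rule = rule, detail = detail)
  meta_key <- paste(metadata$release_id, metadata$bird_id, sep = "/")
  out <- list()
  for (nm in names(tracks)) {
    tr <- tracks[[nm]]
    rid <- attr(tr, "release_id"); bid <- attr(tr, "bird_id")
    row <- metadata[match(paste(rid, bid, sep = "/"), meta_key), ]
    site <- sites[[as.character(row$site)]]
    cleaned <- tryCatch({
      tr2 <- filter_stationary(tr, params)
      trim_homing_segment(tr2, site$release, site$home, params)
    }, routemem_error = function(e) {
      note(rid, bid, class(e)[1], conditionMessage(e)); NULL
    })
    if (!is.null(cleaned)) out[[nm]] <- cleaned
  }
  join_flags <- NULL
  if (check_joining && length(out) > 1) {
    join_flags <- detect_joining(out, params)
    if (nrow(join_flags)) {
      bad <- unique(data.frame(release_id = c(join_flags$release_id_a,
                                              join_flags$release_id_b),
                               bird_id = c(join_flags$bird_id_a,
                                           join_flags$bird_id_b)))
      for (r in seq_len(nrow(bad))) {
        nm <- paste(bad$release_id[r], bad$bird_id[r], sep = "/")
        if (!is.null(out[[nm]])) {
          note(bad$release_id[r], bad$bird_id[r], "joined_flight",
               "proximity to a separately released bird")
          out[[nm]] <- NULL
        }
      }
    }
  }
  # split truncation within each surviving paired release
  paired_rids <- unique(metadata$release_id[metadata$condition == "paired"])
  for (rid in paired_rids) {
    bids <- metadata$bird_id[metadata$release_id == rid]
    nms <- paste(rid, bids, sep = "/")
    if (!all(nms %in% names(out))) next
    res <- tryCatch(truncate_at_split(out[[nms[1]]], out[[nms[2]]], params),
                    routemem_error = function(e) {
                      note(rid, bids[1], class(e)[1], conditionMessage(e))
                      note(rid, bids[2], class(e)[1], conditionMessage(e))
                      NULL
                    })
    if (is.null(res)) { out[[nms[1]]] <- NULL; out[[nms[2]]] <- NULL; next }
    if (!is.na(res$split_time)) {
      note(rid, bids[1], "split_truncation",
           sprintf("truncated at t=%g s", res$split_time))
      note(rid, bids[2], "split_truncation",
           sprintf("truncated at t=%g s", res$split_time))
    }
    out[[nms[1]]] <- res$a; out[[nms[2]]] <- res$b
  }
  exclusions <- if (length(excl)) do.call(rbind, excl) else
    data.frame(release_id = character(0), bird_id = character(0),
               rule = character(0), detail = character(0))
  list(tracks = out, exclusions = exclusions, join_flags = join_flags)
}
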