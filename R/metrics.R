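# Route-memory and efficiency metrics.
#
# Mean NND: mean over fixes of a test track of the distance to the nearest
# fix on any route of a pooled baseline set — the primary route-fidelity
# measure. The 2nd-order mean NND computes the per-baseline-route mean NND
# first and averages those with equal weight, which is robust to a variable
# number of baseline routes. The homing efficiency index (HEI) is beeline
# distance over path length. All distances are spherical great-circle
# (point-to-point, adequate at 1 Hz fix density).

#' Baseline route set
#'
#' Bundles the baseline routes of one pair at one site. Each route is a
#' trajectory (for a paired baseline release, the pooled fixes of both
#' birds count as one route).
#'
#' @param routes list of [trajectory()] objects (1 or more).
#' @param pair_id,site owner identifiers.
#' @return object of class `baseline_set`.
#' @export
baseline_set <- function(routes, pair_id = NA_character_, site = NA_character_) {
  if (length(routes) == 0)
    rm_abort("rm_baseline_error", "empty baseline set for pair %s", pair_id)
  stopifnot(all(vapply(routes, is_trajectory, TRUE)))
  structure(list(routes = routes, pair_id = pair_id, site = site),
            class = "baseline_set")
}

#' @export
print.baseline_set <- function(x, ...) {
  cat(sprintf("<baseline_set> pair %s site %s: %d route(s), %s fixes\n",
              x$pair_id, x$site, length(x$routes),
              paste(vapply(x$routes, nrow, 1L), collapse = "+")))
  invisible(x)
}

# Stack all fixes of a baseline set with a route index column.
.baseline_points <- function(baselines) {
  lat <- unlist(lapply(baselines$routes, `[[`, "lat"), use.names = FALSE)
  lon <- unlist(lapply(baselines$routes, `[[`, "lon"), use.names = FALSE)
  route <- rep(seq_along(baselines$routes),
               vapply(baselines$routes, nrow, 1L))
  list(lat = lat, lon = lon, route = route)
}

# Unit vectors on the sphere for a set of points (n x 3).
.xyz <- function(lat, lon) {
  phi <- lat * pi / 180; lam <- lon * pi / 180
  cbind(cos(phi) * cos(lam), cos(phi) * sin(lam), sin(phi))
}

# Shared workhorse behind both NND metrics: one dot-product matrix against
# the stacked baseline fixes gives the pooled and the per-route nearest
# neighbours (the chord dot-product is monotone in great-circle distance);
# exact haversine distances are evaluated only at the argmins.
.nnd_compute <- function(track, bp, n_routes = max(bp$route),
                         second_order = TRUE) {
  sel <- bp$route <= n_routes
  lat_b <- bp$lat[sel]; lon_b <- bp$lon[sel]; route <- bp$route[sel]
  B <- if (!is.null(bp$xyz)) bp$xyz[sel, , drop = FALSE] else
    .xyz(lat_b, lon_b)
  M <- tcrossprod(.xyz(track$lat, track$lon), B)
  nn_pool <- max.col(M, ties.method = "first")
  mean_pool <- mean(.hav_dist(track$lat, track$lon,
                              lat_b[nn_pool], lon_b[nn_pool]))
  if (!second_order)
    return(c(mean_nnd = mean_pool, so_mean_nnd = NA_real_))
  blocks <- if (!is.null(bp$blocks)) bp$blocks else
    split(seq_along(route), route)
  per_route <- vapply(seq_len(n_routes), function(k) {
    cols <- blocks[[k]]
    nn <- cols[max.col(M[, cols, drop = FALSE], ties.method = "first")]
    mean(.hav_dist(track$lat, track$lon, lat_b[nn], lon_b[nn]))
  }, 0)
  c(mean_nnd = mean_pool, so_mean_nnd = mean(per_route))
}

#' Mean nearest-neighbour distance to a pooled baseline set
#'
#' For each fix of `track`, the minimum distance to the pooled fixes of all
#' baseline routes; returns the arithmetic mean over the track's fixes, in
#' metres.
#'
#' @param track a [trajectory()].
#' @param baselines a [baseline_set()].
#' @return metres (scalar).
#' @export
mean_nnd <- function(track, baselines) {
  if (!inherits(baselines, "baseline_set"))
    rm_abort("rm_baseline_error", "baselines must be a baseline_set")
  unname(.nnd_compute(track, .baseline_points(baselines))["mean_nnd"])
}

#' Second-order mean nearest-neighbour distance
#'
#' Computes the mean NND of `track` against each baseline route separately
#' (nearest fix within that route only) and averages the per-route means
#' with equal weight. Always at least as large as [mean_nnd()] on the same
#' inputs; equal when there is a single baseline route.
#'
#' @inheritParams mean_nnd
#' @return metres (scalar).
#' @export
second_order_mean_nnd <- function(track, baselines) {
  if (!inherits(baselines, "baseline_set"))
    rm_abort("rm_baseline_error", "baselines must be a baseline_set")
  unname(.nnd_compute(track, .baseline_points(baselines))["so_mean_nnd"])
}

#' Homing efficiency index
#'
#' Beeline distance between the first and last fixes divided by the
#' cumulative path length; in (0, 1], with 1 a perfectly straight track.
#'
#' @param track a [trajectory()].
#' @return dimensionless scalar in (0, 1].
#' @export
homing_efficiency <- function(track) {
  pl <- traj_path_length(track)
  if (pl <= 0)
    rm_abort("rm_degenerate_error", "zero path length, HEI undefined")
  n <- nrow(track)
  .hav_dist(track$lat[1], track$lon[1], track$lat[n], track$lon[n]) / pl
}

#' Average the two birds' responses of a paired release
#'
#' One analysis observation per pair per release: the element-wise
#' arithmetic mean of the two birds' raw response metrics. Averaging is on
#' the raw scale; transforms are applied afterwards (see
#' [transform_responses()]).
#'
#' @param row_a,row_b named numeric vectors (or one-row data.frames) of raw
#'   metrics, e.g. `mean_nnd_m`, `so_mean_nnd_m`, `hei`.
#' @return named numeric vector of averaged raw metrics.
#' @export
pair_average <- function(row_a, row_b) {
  a <- unlist(row_a); b <- unlist(row_b)
  if (!identical(names(a), names(b)))
    rm_abort("rm_format_error", "pair_average inputs have different metrics")
  (a + b) / 2
}

#' Response transforms for the mixed models
#'
#' Adds the modelling-scale responses to a metric table: natural logs of
#' the two route-memory metrics and the logit-type transform
#' `log((1 - HEI)/HEI)` of the homing efficiency index. Degenerate values,
#' impossible in noisy field data but possible in synthetic fixtures, are
#' handled conservatively and reported: an NND of 0 is floored at 1 m and
#' an HEI of exactly 1 is clamped to `1 - 1e-6`.
#'
#' @param rows data.frame with columns `mean_nnd_m`, `so_mean_nnd_m`, `hei`
#'   (NAs allowed and propagated).
#' @return `rows` with columns `log_mean_nnd`, `log_so_mean_nnd`,
#'   `hei_transformed` added.
#' @export
transform_responses <- function(rows) {
  clamp_nnd <- function(x) {
    bad <- !is.na(x) & x <= 0
    if (any(bad)) {
      message(sprintf("transform_responses: floored %d zero NND value(s) at 1 m",
                      sum(bad)))
      x[bad] <- 1
    }
    x
  }
  hei <- rows$hei
  bad <- !is.na(hei) & hei >= 1
  if (any(bad)) {
    message(sprintf("transform_responses: clamped %d HEI value(s) at 1 - 1e-6",
                    sum(bad)))
    hei[bad] <- 1 - 1e-6
  }
  rows$log_mean_nnd <- log(clamp_nnd(rows$mean_nnd_m))
  rows$log_so_mean_nnd <- log(clamp_nnd(rows$so_mean_nnd_m))
  rows$hei_transformed <- log((1 - hei) / hei)
  rows
}

#' Build the analysis table of one observation per unit per release
#'
#' Assembles, from preprocessed tracks and metadata, the table the mixed
#' models consume: one row per pair (paired release) or bird (solo
#' release), with the raw and transformed route-memory and efficiency
#' responses. Baseline routes are the pair's tracked paired baseline
#' releases at the same site (both birds' fixes pooled as one route per
#' release). Comparisons at baseline testing use only *previously recorded*
#' baseline routes (strictly smaller release order), so the first tracked
#' baseline release carries efficiency only; at memory testing all
#' baselines are used.
#'
#' @param tracks named list of preprocessed trajectories
#'   (`"release_id/bird_id"`).
#' @param metadata validated metadata.
#' @param second_order also compute the (costlier) 2nd-order mean NND;
#'   setting `FALSE` leaves that column `NA`, which the single-metric
#'   replication studies use.
#' @return data.frame of metric rows (one per unit-release), transformed.
#' @export
build_metric_table <- function(tracks, metadata, second_order = TRUE) {
  meta_key <- paste(metadata$release_id, metadata$bird_id, sep = "/")
  have <- names(tracks)
  # baseline routes per pair-site: tracked paired baseline releases
  base_idx <- metadata$condition == "paired" &
    metadata$testing_time == "baseline"
  base_meta <- unique(metadata[base_idx,
                               c("release_id", "pair_id", "site", "release_order")])
  baselines <- list()  # key pair/site -> list(order=..., route=trajectory)
  for (r in seq_len(nrow(base_meta))) {
    rid <- base_meta$release_id[r]
    bids <- metadata$bird_id[metadata$release_id == rid]
    nms <- paste(rid, bids, sep = "/")
    nms <- nms[nms %in% have]
    if (length(nms) == 0) next
    pts <- do.call(rbind, lapply(nms, function(nm)
      tracks[[nm]][, c("time", "lat", "lon")]))
    pts <- pts[order(pts$time), ]
    # pooled fixes of the release as one route; times made unique for the
    # trajectory invariant (they play no role in the metrics)
    route <- trajectory(seq_len(nrow(pts)) - 1, pts$lat, pts$lon,
                        bird_id = paste(bids, collapse = "+"),
                        release_id = rid)
    key <- paste(base_meta$pair_id[r], base_meta$site[r], sep = "/")
    baselines[[key]] <- c(baselines[[key]],
                          list(list(order = base_meta$release_order[r],
                                    route = route)))
  }
  # stack each pair/site's baseline routes (ordered by release order) once,
  # with cached unit vectors, so per-row comparisons reuse prefixes
  prep <- lapply(baselines, function(bl) {
    bl <- bl[order(vapply(bl, `[[`, 0, "order"))]
    bset <- baseline_set(lapply(bl, `[[`, "route"))
    bp <- .baseline_points(bset)
    bp$xyz <- .xyz(bp$lat, bp$lon)
    bp$blocks <- split(seq_along(bp$route), bp$route)
    list(bp = bp, orders = vapply(bl, `[[`, 0, "order"))
  })
  rel_meta <- unique(metadata[, c("release_id", "pair_id", "site", "treatment",
                                  "condition", "testing_time", "release_order")])
  bids_by_rid <- split(metadata$bird_id, metadata$release_id)
  rl <- list(release_id = as.character(rel_meta$release_id),
             pair_id = as.character(rel_meta$pair_id),
             site = as.character(rel_meta$site),
             treatment = as.character(rel_meta$treatment),
             condition = as.character(rel_meta$condition),
             testing_time = as.character(rel_meta$testing_time),
             release_order = rel_meta$release_order)
  rows <- vector("list", nrow(rel_meta))
  for (r in seq_len(nrow(rel_meta))) {
    rm_ <- lapply(rl, `[[`, r)
    rid <- rm_$release_id
    bids <- bids_by_rid[[rid]]
    nms <- paste(rid, bids, sep = "/")
    present <- nms %in% have
    if (!any(present)) next
    key <- paste(rm_$pair_id, rm_$site, sep = "/")
    pk <- prep[[key]]
    n_routes <- if (is.null(pk)) 0L
    else if (rm_$testing_time == "baseline")
      sum(pk$orders < rm_$release_order)   # previously recorded only
    else length(pk$orders)
    per_bird <- lapply(nms[present], function(nm) {
      tr <- tracks[[nm]]
      nnd <- if (n_routes > 0) .nnd_compute(tr, pk$bp, n_routes, second_order)
             else c(mean_nnd = NA_real_, so_mean_nnd = NA_real_)
      c(mean_nnd_m = unname(nnd["mean_nnd"]),
        so_mean_nnd_m = unname(nnd["so_mean_nnd"]),
        hei = homing_efficiency(tr))
    })
    vals <- if (length(per_bird) == 2) pair_average(per_bird[[1]], per_bird[[2]])
            else per_bird[[1]]
    unit <- if (rm_$condition == "paired") rm_$pair_id else bids[present][1]
    rows[[r]] <- list(unit, rid, rm_$pair_id,
                      if (rm_$condition == "solo") bids[present][1]
                      else NA_character_,
                      as.character(rm_$site), as.character(rm_$treatment),
                      as.character(rm_$condition),
                      as.character(rm_$testing_time), rm_$release_order,
                      n_routes, sum(present), unname(vals["mean_nnd_m"]),
                      unname(vals["so_mean_nnd_m"]), unname(vals["hei"]))
  }
  rows <- rows[!vapply(rows, is.null, TRUE)]
  gc_ <- function(i, cast) cast(unlist(lapply(rows, `[[`, i)))
  tab <- data.frame(
    unit_id = gc_(1, as.character), release_id = gc_(2, as.character),
    pair_id = gc_(3, as.character), bird_id = gc_(4, as.character),
    site = gc_(5, as.character), treatment = gc_(6, as.character),
    condition = gc_(7, as.character), testing_time = gc_(8, as.character),
    release_order = gc_(9, as.integer), n_baselines = gc_(10, as.integer),
    n_tracks = gc_(11, as.integer), mean_nnd_m = gc_(12, as.numeric),
    so_mean_nnd_m = gc_(13, as.numeric), hei = gc_(14, as.numeric))
  transform_responses(tab)
}
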