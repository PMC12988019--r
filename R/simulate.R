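# Synthetic flight generator.
#
# Emulates the paired-release training and memory-testing design: each pair
# owns an idiosyncratic baseline corridor from each release site to the
# loft; tracked baseline releases (paired and solo) fly that corridor with
# GPS jitter; at memory testing each bird has independently forgotten a
# random subset of corridor waypoints (forgotten waypoints collapse toward
# the beeline plus noise), and a pair tested together flies the pooled
# memory of its two members. The generator targets the statistical
# structure of the analysis, not pigeon biomechanics.

#' Simulation configuration
#'
#' Defaults encode the study design: 14 pairs, two release sites at the
#' printed coordinates, three tracked paired baseline releases interspersed
#' with three solo releases per bird at the end of training, an
#' extra-training phase (two tracked paired releases plus one tracked solo
#' release) at the extra-training site, and one memory-testing release per
#' pair per site (paired or solo, randomised with approximately equal
#' counts per treatment and site).
#'
#' @param n_pairs number of pairs.
#' @param sites named list (`A`, `B`) of `list(release = c(lat, lon),
#'   home = c(lat, lon))`.
#' @param n_tracked_baseline_paired tracked paired baseline releases per
#'   pair per site at the end of training.
#' @param n_tracked_baseline_solo tracked solo baseline releases per *bird*
#'   per site at the end of training.
#' @param extra_tracked_baseline_paired tracked paired releases at the end
#'   of extra training (extra-training site only).
#' @param extra_tracked_baseline_solo tracked solo releases (one bird each)
#'   at the end of extra training.
#' @param corridor_waypoints number of interior corridor waypoints.
#' @param corridor_sd_m cross-route idiosyncrasy scale: sd of the
#'   perpendicular Gaussian waypoint offsets about the beeline (metres).
#' @param flight_jitter_sd_m release-to-release route variability: marginal
#'   sd of the perpendicular waypoint jitter drawn once per release and
#'   shared by both birds of a paired release (metres). This is what makes
#'   repeated flights of the same corridor differ at route scale (as real
#'   repeated homing flights do) while keeping within-pair coherence.
#' @param flight_jitter_ar persistence of the route realisation across a
#'   pair's successive releases at a site: the per-release jitter follows a
#'   stationary AR(1) chain with this coefficient, so consecutive flights
#'   resemble each other more than distant ones (slow route drift).
#' @param gps_noise_m sd of iid per-fix GPS jitter (metres).
#' @param step_speed_kmh cruising speed of the constant-speed traversal.
#' @param retention_forgetting,retention_extra probability that a bird
#'   retains an interior waypoint at memory testing, per treatment.
#' @param retention_correlation within-pair correlation of waypoint
#'   retention (Gaussian copula; 0 = independent forgetting).
#' @param lost_segment_sd_m sd of the perpendicular offset of a forgotten
#'   waypoint about the beeline (metres).
#' @param pooling_rule `"distributed"` (waypoint-wise union of the two
#'   memories) or `"leader"` (the member with more retained waypoints).
#' @param efficiency_decay multiplier on the perpendicular offsets of
#'   memory-testing routes (1 = no extra tortuosity).
#' @param sample_interval_s GPS sampling interval (nominally 1 s; the
#'   replication studies in the vignette use 5 s).
#' @param dawdle_s,approach_s seconds of slow pre-departure and loft
#'   approach movement injected so the speed filter and trimming rules have
#'   work to do on every track.
#' @param release_spacing_s wall-clock spacing between consecutive releases.
#' @param seed integer seed; the whole experiment is reproducible from it.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_pairs = 14,
                       sites = list(
                         A = list(release = c(51.7527778, -1.42375),
                                  home = c(51.7828602, -1.3173753)),
                         B = list(release = c(51.8303056, -1.3915),
                                  home = c(51.7828602, -1.3173753))),
                       n_tracked_baseline_paired = 3,
                       n_tracked_baseline_solo = 3,
                       extra_tracked_baseline_paired = 2,
                       extra_tracked_baseline_solo = 1,
                       corridor_waypoints = 12, corridor_sd_m = 400,
                       flight_jitter_sd_m = 150, flight_jitter_ar = 0.7,
                       gps_noise_m = 15, step_speed_kmh = 65,
                       retention_forgetting = 0.6, retention_extra = 0.9,
                       retention_correlation = 0, lost_segment_sd_m = 800,
                       pooling_rule = c("distributed", "leader"),
                       efficiency_decay = 1, sample_interval_s = 1,
                       dawdle_s = 40, approach_s = 30,
                       release_spacing_s = 600, seed = 1) {
  pooling_rule <- match.arg(pooling_rule)
  cfg <- as.list(environment())
  probs <- c(retention_forgetting, retention_extra)
  if (any(probs < 0 | probs > 1) ||
      retention_correlation < 0 || retention_correlation > 1)
    rm_abort("rm_config_error", "retention probabilities/correlation must be in [0,1]")
  if (flight_jitter_ar < 0 || flight_jitter_ar >= 1)
    rm_abort("rm_config_error", "flight_jitter_ar must be in [0, 1)")
  if (n_pairs < 2 || corridor_waypoints < 1 ||
      n_tracked_baseline_paired < 1 || n_tracked_baseline_solo < 0)
    rm_abort("rm_config_error", "inconsistent design counts")
  if (corridor_sd_m < 0 || gps_noise_m < 0 || lost_segment_sd_m < 0 ||
      flight_jitter_sd_m < 0 ||
      step_speed_kmh <= 0 || sample_interval_s <= 0)
    rm_abort("rm_config_error", "scales must be non-negative and speed positive")
  class(cfg) <- "sim_config"
  cfg
}

#' Generate a pair's baseline corridor
#'
#' A smooth waypoint chain from release to home: interior waypoints sit at
#' equal arc fractions of the beeline with independent perpendicular
#' Gaussian offsets (sd `corridor_sd_m`); the endpoints are fixed. Uses the
#' current RNG stream.
#'
#' @param release,home `c(lat, lon)`.
#' @param config a [sim_config()].
#' @return object of class `sim_corridor`: waypoint fractions, perpendicular
#'   offsets (m) and the site geometry.
#' @export
make_baseline_corridor <- function(release, home, config = sim_config()) {
  K <- config$corridor_waypoints
  perp <- c(0, stats::rnorm(K, 0, config$corridor_sd_m), 0)
  structure(list(release = release, home = home,
                 frac = seq(0, 1, length.out = K + 2), perp = perp),
            class = "sim_corridor")
}

# Local (east, north) coordinates of a corridor's waypoints.
.corridor_local <- function(corr) {
  endp <- .local_from_geo(corr$home[1], corr$home[2],
                          corr$release[1], corr$release[2])
  L <- sqrt(sum(endp^2))
  u <- endp / L                       # along-beeline unit vector
  nvec <- c(-u[2], u[1])              # left-hand normal
  along <- corr$frac * L
  cbind(east = along * u[1] + corr$perp * nvec[1],
        north = along * u[2] + corr$perp * nvec[2])
}

#' Degrade a route memory by waypoint forgetting
#'
#' Each interior waypoint is independently retained with probability
#' `retention_p`; a forgotten waypoint is displaced toward the beeline,
#' landing at a fresh perpendicular offset drawn with sd
#' `lost_segment_sd_m`. Endpoints are always retained. A retention mask can
#' be supplied (see [retention_masks()]) to correlate forgetting across
#' pair members.
#'
#' @param corridor a `sim_corridor`.
#' @param retention_p retention probability in `[0, 1]`.
#' @param config a [sim_config()].
#' @param mask optional logical vector (length = interior waypoints); drawn
#'   from `retention_p` if missing.
#' @return list: `corridor` (degraded), `retained` (logical mask).
#' @export
forget_route <- function(corridor, retention_p, config = sim_config(),
                         mask = NULL) {
  if (retention_p < 0 || retention_p > 1)
    rm_abort("rm_config_error", "retention_p must be in [0,1]")
  K <- length(corridor$frac) - 2
  if (is.null(mask)) mask <- stats::runif(K) < retention_p
  if (length(mask) != K)
    rm_abort("rm_config_error", "mask length must equal interior waypoint count")
  perp <- corridor$perp
  lost <- which(!mask) + 1
  perp[lost] <- stats::rnorm(length(lost), 0, config$lost_segment_sd_m)
  out <- corridor; out$perp <- perp
  list(corridor = out, retained = mask)
}

#' Correlated within-pair retention masks
#'
#' Draws one retention mask per pair member with marginal retention
#' probability `p` and within-pair correlation `rho` via a shared latent
#' Gaussian (Gaussian copula), so independent (`rho = 0`) and fully shared
#' (`rho = 1`) forgetting are both reachable.
#'
#' @param k number of interior waypoints.
#' @param p retention probability.
#' @param rho latent correlation in `[0, 1]`.
#' @return list of two logical vectors.
#' @export
retention_masks <- function(k, p, rho = 0) {
  shared <- stats::rnorm(k)
  lapply(1:2, function(b) {
    z <- sqrt(rho) * shared + sqrt(1 - rho) * stats::rnorm(k)
    stats::pnorm(z) < p
  })
}

#' Pool the route memories of a pair
#'
#' Under the `"distributed"` rule the pooled route keeps, at each waypoint,
#' any member's retained value (the average when both retained it — which
#' is the original corridor waypoint — and the average of the two degraded
#' values when neither did). Under `"leader"` the pooled route is simply
#' the waypoint chain of the member with the larger retained count (ties go
#' to the first member).
#'
#' @param mem_a,mem_b `sim_corridor` objects from [forget_route()].
#' @param mask_a,mask_b the members' retention masks.
#' @param rule `"distributed"` or `"leader"`.
#' @return list: `corridor` (pooled), `retained` (waypoints retained by at
#'   least one member).
#' @export
pool_pair_memory <- function(mem_a, mem_b, mask_a, mask_b,
                             rule = c("distributed", "leader")) {
  rule <- match.arg(rule)
  if (length(mem_a$perp) != length(mem_b$perp))
    rm_abort("rm_config_error", "pair memories have different waypoint counts")
  if (rule == "leader") {
    lead <- if (sum(mask_b) > sum(mask_a)) mem_b else mem_a
    lead_mask <- if (sum(mask_b) > sum(mask_a)) mask_b else mask_a
    return(list(corridor = lead, retained = lead_mask))
  }
  K <- length(mem_a$frac) - 2
  perp <- mem_a$perp
  for (i in seq_len(K)) {
    j <- i + 1
    perp[j] <- if (mask_a[i] && mask_b[i]) (mem_a$perp[j] + mem_b$perp[j]) / 2
    else if (mask_a[i]) mem_a$perp[j]
    else if (mask_b[i]) mem_b$perp[j]
    else (mem_a$perp[j] + mem_b$perp[j]) / 2
  }
  out <- mem_a; out$perp <- perp
  list(corridor = out, retained = mask_a | mask_b)
}

#' Realise a GPS track from a waypoint chain
#'
#' Constant-speed traversal of the corridor polyline sampled at the
#' configured interval, with iid Gaussian GPS jitter per fix, preceded by a
#' slow pre-departure dawdle at the release point and followed by a slow
#' loft approach, so the stationary-point filter and homing-segment
#' trimming are exercised on every synthetic track.
#'
#' @param corridor a `sim_corridor`.
#' @param config a [sim_config()].
#' @param bird_id,release_id,start_offset_s identity attributes.
#' @return a [trajectory()].
#' @export
realize_flight <- function(corridor, config = sim_config(),
                           bird_id = NA_character_,
                           release_id = NA_character_,
                           start_offset_s = 0) {
  wp <- .corridor_local(corridor)
  seg <- sqrt(diff(wp[, 1])^2 + diff(wp[, 2])^2)
  cum <- c(0, cumsum(seg))
  v <- config$step_speed_kmh / 3.6
  dt <- config$sample_interval_s
  t_fly <- seq(0, cum[length(cum)] / v, by = dt)
  s <- pmin(v * t_fly, cum[length(cum)])
  idx <- pmin(findInterval(s, cum, all.inside = TRUE), length(cum) - 1)
  w <- (s - cum[idx]) / (cum[idx + 1] - cum[idx])
  fx <- wp[idx, 1] + w * (wp[idx + 1, 1] - wp[idx, 1])
  fy <- wp[idx, 2] + w * (wp[idx + 1, 2] - wp[idx, 2])
  n_daw <- max(0, floor(config$dawdle_s / dt))
  n_app <- max(0, floor(config$approach_s / dt))
  drift <- function(n, x0, y0) {
    if (n == 0) return(NULL)
    cbind(x0 + cumsum(stats::rnorm(n, 0, 1.5 * dt)),
          y0 + cumsum(stats::rnorm(n, 0, 1.5 * dt)))
  }
  daw <- drift(n_daw, 0, 0)
  app <- drift(n_app, fx[length(fx)], fy[length(fy)])
  x <- c(if (n_daw) rev(daw[, 1]), fx, if (n_app) app[, 1])
  y <- c(if (n_daw) rev(daw[, 2]), fy, if (n_app) app[, 2])
  n <- length(x)
  x <- x + stats::rnorm(n, 0, config$gps_noise_m)
  y <- y + stats::rnorm(n, 0, config$gps_noise_m)
  geo <- .geo_from_local(x, y, corridor$release[1], corridor$release[2])
  .new_trajectory(seq_len(n) * dt - dt, unname(geo[, "lat"]),
                  unname(geo[, "lon"]), bird_id = bird_id,
                  release_id = release_id, start_offset_s = start_offset_s)
}

#' Generate a full synthetic experiment
#'
#' Produces all tracks, the release-metadata table and a ground-truth
#' ledger for one simulated experiment, fully reproducible from
#' `config$seed`. Treatments are assigned so each pair does one treatment
#' per site with equal counts per treatment and site; memory-testing
#' condition (paired vs solo) is randomised within each treatment-site
#' cell with approximately equal counts. Baseline flights fly the pair's
#' corridor (retention 1); memory flights fly the treatment-specific
#' degraded (solo) or pooled (paired) memory.
#'
#' @param config a [sim_config()].
#' @return list: `tracks` (named list `"release_id/bird_id"`), `metadata`
#'   (validated data.frame), `ledger` (per-track truth), `config`.
#' @export
generate_experiment <- function(config = sim_config()) {
  old_seed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(config$seed)

  np <- config$n_pairs
  pair_ids <- sprintf("P%02d", seq_len(np))
  bird_of <- function(p, m) paste0(p, c("a", "b")[m])
  # one treatment per site per pair, balanced across pairs
  forg_at_A <- sample(rep(c(TRUE, FALSE), length.out = np))
  treat <- function(p_idx, site)
    if ((site == "A") == forg_at_A[p_idx]) "forgetting" else "extra_training"
  # memory-test condition balanced within site x treatment cells
  mem_paired <- matrix(NA, np, 2, dimnames = list(pair_ids, c("A", "B")))
  for (s in c("A", "B")) for (tr in c("forgetting", "extra_training")) {
    idx <- which(vapply(seq_len(np), function(i) treat(i, s) == tr, TRUE))
    mem_paired[idx, s] <- sample(rep(c(TRUE, FALSE), length.out = length(idx)))
  }
  corridors <- list()
  for (i in seq_len(np)) for (s in c("A", "B"))
    corridors[[paste(pair_ids[i], s, sep = "/")]] <-
      make_baseline_corridor(config$sites[[s]]$release, config$sites[[s]]$home,
                             config)
  tracks <- list()
  rec <- list()   # one record per bird-track, flattened at the end
  jitter_state <- list()  # per pair/site AR route-drift state
  order_ctr <- c(A = 0L, B = 0L)
  add_release <- function(p_idx, site, condition, testing_time, members,
                          corridor_list, retained_counts, flown) {
    order_ctr[site] <<- order_ctr[site] + 1L
    rid <- sprintf("R%s%04d", site, order_ctr[site])
    off <- (if (site == "A") 0 else 1e6) +
      order_ctr[site] * config$release_spacing_s
    if (config$flight_jitter_sd_m > 0) {
      # one route realisation per release, shared by both members, drifting
      # as a stationary AR(1) chain across the pair's releases at this site
      key <- paste(pair_ids[p_idx], site, sep = "/")
      phi <- config$flight_jitter_ar
      innov <- stats::rnorm(config$corridor_waypoints, 0,
                            config$flight_jitter_sd_m)
      jit <- if (is.null(jitter_state[[key]])) innov
             else phi * jitter_state[[key]] + sqrt(1 - phi^2) * innov
      jitter_state[[key]] <<- jit
      corridor_list <- lapply(corridor_list, function(cr) {
        k <- length(cr$perp)
        cr$perp[2:(k - 1)] <- cr$perp[2:(k - 1)] + jit
        cr
      })
    }
    for (m in seq_along(members)) {
      bid <- members[m]
      tracks[[paste(rid, bid, sep = "/")]] <<-
        realize_flight(corridor_list[[m]], config, bird_id = bid,
                       release_id = rid, start_offset_s = off)
      rec[[length(rec) + 1]] <<-
        list(rid, bid, pair_ids[p_idx], site, treat(p_idx, site), condition,
             testing_time, order_ctr[site], off, flown, retained_counts[m])
    }
    rid
  }
  K <- config$corridor_waypoints
  for (s in c("A", "B")) {
    # end-of-training tracked releases: paired interspersed with solo rounds
    for (i in seq_len(np)) {
      corr <- corridors[[paste(pair_ids[i], s, sep = "/")]]
      rounds <- max(config$n_tracked_baseline_paired,
                    config$n_tracked_baseline_solo)
      for (r in seq_len(rounds)) {
        if (r <= config$n_tracked_baseline_paired)
          add_release(i, s, "paired", "baseline", bird_of(pair_ids[i], 1:2),
                      list(corr, corr), c(K, K), "corridor")
        if (r <= config$n_tracked_baseline_solo) {
          add_release(i, s, "solo", "baseline", bird_of(pair_ids[i], 1),
                      list(corr), K, "corridor")
          add_release(i, s, "solo", "baseline", bird_of(pair_ids[i], 2),
                      list(corr), K, "corridor")
        }
      }
      # extra-training tracked releases at the extra-training site
      if (treat(i, s) == "extra_training") {
        for (r in seq_len(config$extra_tracked_baseline_paired))
          add_release(i, s, "paired", "baseline", bird_of(pair_ids[i], 1:2),
                      list(corr, corr), c(K, K), "corridor")
        for (r in seq_len(config$extra_tracked_baseline_solo))
          add_release(i, s, "solo", "baseline",
                      bird_of(pair_ids[i], 1 + (r - 1) %% 2),
                      list(corr), K, "corridor")
      }
    }
    # memory testing
    for (i in seq_len(np)) {
      corr <- corridors[[paste(pair_ids[i], s, sep = "/")]]
      p_ret <- if (treat(i, s) == "forgetting") config$retention_forgetting
               else config$retention_extra
      masks <- retention_masks(K, p_ret, config$retention_correlation)
      mem_a <- forget_route(corr, p_ret, config, mask = masks[[1]])
      mem_b <- forget_route(corr, p_ret, config, mask = masks[[2]])
      decay <- function(cr) {
        cr$perp <- cr$perp * config$efficiency_decay; cr
      }
      if (mem_paired[i, s]) {
        pooled <- pool_pair_memory(mem_a$corridor, mem_b$corridor,
                                   masks[[1]], masks[[2]],
                                   rule = config$pooling_rule)
        add_release(i, s, "paired", "memory_testing",
                    bird_of(pair_ids[i], 1:2),
                    list(decay(pooled$corridor), decay(pooled$corridor)),
                    rep(sum(pooled$retained), 2), "pooled")
      } else {
        add_release(i, s, "solo", "memory_testing", bird_of(pair_ids[i], 1),
                    list(decay(mem_a$corridor)), sum(masks[[1]]), "own")
        add_release(i, s, "solo", "memory_testing", bird_of(pair_ids[i], 2),
                    list(decay(mem_b$corridor)), sum(masks[[2]]), "own")
      }
    }
  }
  col <- function(i, as = as.character) as(vapply(rec, function(r)
    as.character(r[[i]]), ""))
  metadata <- data.frame(
    release_id = col(1), bird_id = col(2), pair_id = col(3), site = col(4),
    treatment = col(5), condition = col(6), testing_time = col(7),
    release_order = col(8, as.integer), release_start_s = col(9, as.numeric))
  ledger <- data.frame(
    release_id = col(1), bird_id = col(2), pair_id = col(3), site = col(4),
    treatment = col(5), condition = col(6), testing_time = col(7),
    flown = col(10), n_interior = config$corridor_waypoints,
    retained_count = col(11, as.integer))
  metadata <- validate_metadata(metadata)
  list(tracks = tracks, metadata = metadata, ledger = ledger,
       config = config)
}

#' Write a generated experiment to disk
#'
#' Tracks as CSV (one file per bird-release), the metadata table as CSV and
#' the ground-truth ledger as JSON-compatible CSV.
#'
#' @param experiment result of [generate_experiment()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_experiment <- function(experiment, dir) {
  dir.create(file.path(dir, "tracks"), recursive = TRUE, showWarnings = FALSE)
  for (nm in names(experiment$tracks))
    write_track(experiment$tracks[[nm]],
                file.path(dir, "tracks", paste0(gsub("/", "_", nm), ".csv")))
  utils::write.csv(experiment$metadata, file.path(dir, "metadata.csv"),
                   row.names = FALSE)
  utils::write.csv(experiment$ledger, file.path(dir, "ledger.csv"),
                   row.names = FALSE)
  invisible(dir)
}
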