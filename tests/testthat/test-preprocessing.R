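test_that("point speeds match an independent per-segment haversine loop", {
  # 20 m in 1 s is 72 km/h at both fixes
  tr <- local_traj(c(0, 20), c(0, 0))
  expect_equal(point_speeds(tr), c(72, 72), tolerance = 1e-6)
  # coincident consecutive fixes give zero speed
  tr0 <- local_traj(c(0, 10, 10), c(0, 0, 0))
  expect_equal(point_speeds(tr0)[3], 0)

  set.seed(5)
  tr <- random_traj(100)
  v <- point_speeds(tr)
  expect_length(v, 100)
  v_oracle <- vapply(2:100, function(i)
    oracle_dist(tr$lat[i - 1], tr$lon[i - 1], tr$lat[i], tr$lon[i]) /
      (tr$time[i] - tr$time[i - 1]) * 3.6, 0)
  expect_equal(v[-1], v_oracle, tolerance = 1e-9)
  expect_equal(v[1], v_oracle[1], tolerance = 1e-9)
})

test_that("speed filter keeps exactly the fast-fix index set", {
  # uniform 60 km/h flight is untouched
  east <- seq(0, 1600, length.out = 97)   # 16.7 m/s = 60 km/h
  tr <- local_traj(east, rep(0, 97))
  expect_equal(nrow(filter_stationary(tr)), 97)

  # stationary tail removed, flight intact
  east <- c(seq(0, 2000, by = 20), rep(2000, 120) + rnorm(120, 0, 0.5))
  tr <- local_traj(east, rep(0, length(east)))
  out <- filter_stationary(tr)
  expect_lt(nrow(out), length(east))
  expect_true(all(out$time <= 101))

  # survivor set equals the independently computed index set
  set.seed(9)
  step <- runif(120, 0, 17)   # straddles the 30 km/h = 8.33 m/s threshold
  tr <- local_traj(cumsum(step), rep(0, 120))
  v <- point_speeds(tr)
  out <- filter_stationary(tr)
  expect_equal(out$time, tr$time[v >= 30])

  slow <- local_traj(seq(0, 10, length.out = 30), rep(0, 30))
  expect_error(filter_stationary(slow), class = "rm_degenerate_error")
})

test_that("homing trim runs from final 2 km departure to first 500 m entry", {
  release <- c(51.7527778, -1.42375)
  home <- LOFT
  # straight synthetic flight release -> home with slow dawdle and approach
  cfg <- sim_config(corridor_sd_m = 0, gps_noise_m = 0, seed = 1)
  corr <- make_baseline_corridor(release, home, cfg)
  tr <- realize_flight(corr, cfg)
  out <- trim_homing_segment(tr, release, home)
  d_rel <- geo_distance(out$lat, out$lon, release[1], release[2],
                        method = "haversine")
  d_home <- geo_distance(out$lat, out$lon, home[1], home[2],
                         method = "haversine")
  expect_lte(d_rel[1], 2000)
  expect_true(all(d_rel[-1] > 2000))
  expect_lte(d_home[length(d_home)], 500)
  expect_true(all(d_home[-length(d_home)] > 500))
  # indices match a brute-force scan of the distance series
  d_all_rel <- geo_distance(tr$lat, tr$lon, release[1], release[2],
                            method = "haversine")
  i_start <- max(which(d_all_rel <= 2000))
  d_all_home <- geo_distance(tr$lat, tr$lon, home[1], home[2],
                             method = "haversine")
  j_end <- min(which(d_all_home <= 500 & seq_along(d_all_home) > i_start))
  expect_equal(out$time, tr$time[i_start:j_end])

  # a loop back inside 2 km delays the trim start to the *final* departure
  east <- c(seq(0, 2500, by = 100), seq(2400, 1800, by = -100),
            seq(1900, 8000, by = 100))
  north <- rep(0, length(east))
  lp <- local_traj(east, north, origin = release)
  home2_east <- 8000
  home2 <- c(release[1], release[2] + home2_east /
               (M_PER_DEG * cos(release[1] * pi / 180)))
  out2 <- trim_homing_segment(lp, release, home2)
  d2 <- geo_distance(out2$lat, out2$lon, release[1], release[2],
                     method = "haversine")
  expect_lte(d2[1], 2000)
  expect_true(all(d2[-1] > 2000))
  # the kept segment starts after the loop-back, i.e. beyond its time
  expect_gte(out2$time[1], 32)

  # never entering the home radius is a non-homing error
  short <- local_traj(seq(0, 7000, by = 100), rep(0, 71), origin = release)
  far_home <- c(release[1], release[2] + 7600 /
                  (M_PER_DEG * cos(release[1] * pi / 180)))
  expect_error(trim_homing_segment(short, release, far_home),
               class = "rm_nonhoming_error")
  # never leaving the release radius is a non-departure error
  near <- local_traj(seq(0, 1000, by = 50), rep(0, 21), origin = release)
  expect_error(trim_homing_segment(near, release, far_home),
               class = "rm_nondeparture_error")
})

test_that("joined-flight detection flags close tracks and honours clocks", {
  mk <- function(offset_m, t0, rid, n = 301) {
    local_traj(seq(0, 6000, length.out = n), rep(offset_m, n),
               time = seq(0, 300, length.out = n),
               bird_id = paste0("b", rid), release_id = rid,
               start_offset_s = t0)
  }
  # parallel tracks 40 m apart with overlapping clocks: flagged both ways
  flags <- detect_joining(list(mk(0, 0, "r1"), mk(40, 0, "r2")))
  expect_equal(nrow(flags), 2)
  expect_setequal(flags$release_id_a, c("r1", "r2"))
  expect_gt(flags$n_flagged[1], 0)

  # same geometry 10 km apart: nothing
  expect_equal(nrow(detect_joining(list(mk(0, 0, "r1"), mk(10000, 0, "r2")))),
               0)
  # same geometry, disjoint release windows: nothing
  expect_equal(nrow(detect_joining(list(mk(0, 0, "r1"), mk(40, 4000, "r2")))),
               0)
  # missing wall clock offsets cannot be compared
  t_na <- mk(0, NA_real_, "r1")
  expect_error(detect_joining(list(t_na, mk(40, 0, "r2"))),
               class = "rm_compare_error")

  # oracle: enumerate all (sample, fix) pairs for a wiggly pair of tracks
  set.seed(31)
  a <- local_traj(seq(0, 3000, by = 20) + rnorm(151, 0, 5),
                  rnorm(151, 0, 30), time = 0:150,
                  bird_id = "ba", release_id = "ra", start_offset_s = 0)
  b <- local_traj(seq(0, 3000, by = 20) + rnorm(151, 0, 5),
                  rnorm(151, 0, 30), time = 0:150,
                  bird_id = "bb", release_id = "rb", start_offset_s = 40)
  flags <- detect_joining(list(a, b))
  expect_flag <- FALSE
  for (k in which(a$time %% 30 == 0)) {
    cand <- which(abs((b$time + 40) - (a$time[k] + 0)) <= 15)
    if (length(cand) &&
        min(oracle_dist(a$lat[k], a$lon[k], b$lat[cand], b$lon[cand])) <= 50)
      expect_flag <- TRUE
  }
  expect_equal(any(flags$release_id_a == "ra"), expect_flag)
})

test_that("split truncation finds the last un-reestablished separation", {
  mk_pair <- function(gap) {
    n <- length(gap)
    a <- local_traj(seq(0, by = 18, length.out = n), rep(0, n),
                    time = 0:(n - 1), bird_id = "a", release_id = "r")
    b <- local_traj(seq(0, by = 18, length.out = n), gap,
                    time = 0:(n - 1), bird_id = "b", release_id = "r")
    list(a = a, b = b)
  }
  # diverges at t = 400 for good
  gap <- c(rep(10, 400), rep(300, 200))
  p <- mk_pair(gap)
  res <- truncate_at_split(p$a, p$b)
  expect_equal(res$split_time, 400)
  expect_true(all(res$a$time < 400))
  expect_equal(nrow(res$a), 400)
  # brute-force scan over the distance series agrees
  d <- oracle_dist(p$a$lat, p$a$lon, p$b$lat, p$b$lon)
  far <- which(d > 150); near <- which(d <= 150)
  expect_equal(res$split_time,
               p$a$time[min(far[far > max(near)])])

  # transient 200 m excursion at t = 100 does not split; t = 500 does
  gap <- rep(10, 650)
  gap[101:130] <- 200
  gap[501:650] <- 400
  p <- mk_pair(gap)
  expect_equal(truncate_at_split(p$a, p$b)$split_time, 500)

  # never apart: returned whole
  p <- mk_pair(rep(120, 300))
  res <- truncate_at_split(p$a, p$b)
  expect_true(is.na(res$split_time))
  expect_equal(nrow(res$a), 300)

  # disjoint time bases cannot be compared
  b2 <- local_traj(c(0, 18), c(0, 0), time = c(1000, 1001),
                   bird_id = "b", release_id = "r")
  expect_error(truncate_at_split(p$a, b2), class = "rm_compare_error")
})

test_that("preprocessing is order-stable and logs every exclusion once", {
  cfg <- replication_config(seed = 33, n_pairs = 3)
  ex <- generate_experiment(cfg)
  prep <- preprocess_experiment(ex$tracks, ex$metadata, cfg$sites,
                                check_joining = TRUE)
  # survivors are subsequences of their raw inputs
  for (nm in names(prep$tracks)[1:10]) {
    raw <- ex$tracks[[nm]]
    out <- prep$tracks[[nm]]
    expect_true(all(out$time %in% raw$time))
    expect_false(is.unsorted(out$time))
  }
  # ledger rows are unique per (release, bird, rule)
  if (nrow(prep$exclusions))
    expect_false(any(duplicated(prep$exclusions[, c("release_id", "bird_id",
                                                    "rule")])))
})
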