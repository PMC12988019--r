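# Shared fixture builders and independent oracles.

LOFT <- c(51.7828602, -1.3173753)
STANTON <- c(51.7527778, -1.42375)
HANBOROUGH <- c(51.8303056, -1.3915)

M_PER_DEG <- 6371008.8 * pi / 180

# Build a trajectory from local east/north metre offsets about an origin.
local_traj <- function(east, north, origin = LOFT, time = seq_along(east) - 1,
                       bird_id = "b", release_id = "r", start_offset_s = 0) {
  lat <- origin[1] + north / M_PER_DEG
  lon <- origin[2] + east / (M_PER_DEG * cos(origin[1] * pi / 180))
  trajectory(time, lat, lon, bird_id = bird_id, release_id = release_id,
             start_offset_s = start_offset_s)
}

# Random wiggly track near the study area.
random_traj <- function(n, scale_m = 2000, origin = LOFT, ...) {
  local_traj(cumsum(rnorm(n, 0, scale_m / sqrt(n))),
             cumsum(rnorm(n, 0, scale_m / sqrt(n))), origin = origin, ...)
}

# Independent scalar geodesic via geosphere (haversine convention), used by
# the brute-force metric oracles.
oracle_dist <- function(lat1, lon1, lat2, lon2) {
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2),
                           r = 6371008.8)
}

# Brute-force double-loop oracles over every (track fix, baseline fix) pair.
oracle_mean_nnd <- function(track, baselines) {
  mins <- vapply(seq_len(nrow(track)), function(i) {
    best <- Inf
    for (r in baselines$routes)
      best <- min(best, min(oracle_dist(track$lat[i], track$lon[i],
                                        r$lat, r$lon)))
    best
  }, 0)
  mean(mins)
}

oracle_so_mean_nnd <- function(track, baselines) {
  per_route <- vapply(baselines$routes, function(r) {
    mean(vapply(seq_len(nrow(track)), function(i)
      min(oracle_dist(track$lat[i], track$lon[i], r$lat, r$lon)), 0))
  }, 0)
  mean(per_route)
}

oracle_hei <- function(track) {
  n <- nrow(track)
  step <- oracle_dist(track$lat[-n], track$lon[-n], track$lat[-1],
                      track$lon[-1])
  oracle_dist(track$lat[1], track$lon[1], track$lat[n], track$lon[n]) /
    sum(step)
}

# Dense REML evaluator, independent of the package internals: builds the
# full n x n covariance and computes the restricted log-likelihood directly.
oracle_reml_loglik <- function(s2e, s2_comp, y, X, Zs) {
  n <- length(y); p <- ncol(X)
  V <- diag(s2e, n)
  for (i in seq_along(Zs)) V <- V + s2_comp[i] * tcrossprod(Zs[[i]])
  L <- chol(V)
  Vi_y <- backsolve(L, backsolve(L, y, transpose = TRUE))
  Vi_X <- backsolve(L, backsolve(L, X, transpose = TRUE))
  XtViX <- crossprod(X, Vi_X)
  beta <- solve(XtViX, crossprod(X, Vi_y))
  r <- y - X %*% beta
  Vi_r <- backsolve(L, backsolve(L, r, transpose = TRUE))
  -0.5 * ((n - p) * log(2 * pi) + 2 * sum(log(diag(L))) +
            determinant(XtViX, logarithm = TRUE)$modulus + sum(r * Vi_r))
}

# Small multimember layout used by several model tests: n_obs observations
# over n_pairs pairs (2 birds each), random mix of paired/solo rows.
toy_multimember <- function(n_obs = 40, n_pairs = 4, beta = c(1, 0.5, -0.3),
                            s2e = 1, s2i = 0.5, s2p = 0.25) {
  birds <- paste0("b", seq_len(2 * n_pairs))
  pairs <- paste0("p", seq_len(n_pairs))
  pair_of <- rep(pairs, each = 2)
  X <- cbind(1, rnorm(n_obs), rbinom(n_obs, 1, 0.5))
  colnames(X) <- c("(Intercept)", "x1", "x2")
  Z1 <- matrix(0, n_obs, length(birds), dimnames = list(NULL, birds))
  Z2 <- matrix(0, n_obs, length(pairs), dimnames = list(NULL, pairs))
  for (i in seq_len(n_obs)) {
    p <- sample(n_pairs, 1)
    Z2[i, p] <- 1
    if (runif(1) < 0.5) {
      Z1[i, 2 * p - 1] <- 0.5; Z1[i, 2 * p] <- 0.5
    } else {
      Z1[i, 2 * p - sample(0:1, 1)] <- 1
    }
  }
  u1 <- rnorm(length(birds), 0, sqrt(s2i))
  u2 <- rnorm(length(pairs), 0, sqrt(s2p))
  y <- drop(X %*% beta + Z1 %*% u1 + Z2 %*% u2 + rnorm(n_obs, 0, sqrt(s2e)))
  list(y = y, X = X, Zs = list(individual = Z1, pair = Z2))
}
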