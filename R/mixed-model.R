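# Multimember linear mixed-effects models fitted by REML.
#
# Model: y = X beta + Z1 u1 + Z2 u2 + e, with u1 individual intercepts
# loaded through fractional membership weights (a paired observation loads
# 0.5 on each member bird; a solo observation loads 1 on its bird), u2 pair
# intercepts, and independent residuals. The marginal covariance is
#   V = sigma2 * (I + g1 Z1 Z1' + g2 Z2 Z2'),
# and the REML criterion is maximised over the log variance ratios
# (g1, g2) with sigma2 profiled out. All linear algebra is done in the
# q-dimensional random-effect space via the Woodbury identity, so a
# criterion evaluation costs O(q^3) regardless of the number of
# observations.

#' Model specification for the factorial analysis
#'
#' Fixed effects: `response ~ condition * treatment * testing_time + site`
#' (full three-way factorial of release condition, treatment and testing
#' time, plus a site main effect), with treatment (dummy) coding against
#' the given reference levels. Random effects: multimember individual
#' intercepts and pair intercepts. Changing the reference levels and
#' refitting is how planned contrasts (simple effects) are read off.
#'
#' @param response name of the response column (a transformed metric,
#'   e.g. `"log_mean_nnd"`).
#' @param ref_levels named list of reference levels for `condition`,
#'   `treatment`, `testing_time`, `site`.
#' @param paired_weight membership weight of each member bird in a paired
#'   observation (the two weights are this value each; default 0.5 so rows
#'   of the membership matrix sum to 1).
#' @return list of class `model_spec`.
#' @export
model_spec <- function(response = "log_mean_nnd",
                       ref_levels = list(condition = "paired",
                                         treatment = "forgetting",
                                         testing_time = "baseline",
                                         site = "A"),
                       paired_weight = 0.5) {
  for (f in names(.META_LEVELS)) {
    if (is.null(ref_levels[[f]])) ref_levels[[f]] <- .META_LEVELS[[f]][1]
    if (!ref_levels[[f]] %in% .META_LEVELS[[f]])
      rm_abort("rm_domain_error", "invalid reference level %s for %s",
               ref_levels[[f]], f)
  }
  structure(list(response = response, ref_levels = ref_levels,
                 paired_weight = paired_weight), class = "model_spec")
}

#' Build the design matrices of the multimember model
#'
#' @param rows metric table (see [build_metric_table()]); rows with a
#'   missing response are dropped.
#' @param spec a [model_spec()].
#' @param members pair membership lookup (see [pair_members()]), needed to
#'   resolve a paired observation to its two birds.
#' @return list with `y`, `X`, `Z_individual` (rows sum to 1; 0.5/0.5 on
#'   paired rows), `Z_pair` (indicator), and the model frame `data`.
#' @export
build_design <- function(rows, spec, members) {
  keep <- !is.na(rows[[spec$response]])
  df <- rows[keep, , drop = FALSE]
  if (nrow(df) == 0)
    rm_abort("rm_degenerate_error", "no complete observations for %s",
             spec$response)
  for (f in names(.META_LEVELS)) {
    df[[f]] <- factor(as.character(df[[f]]), levels = .META_LEVELS[[f]])
    df[[f]] <- stats::relevel(df[[f]], ref = spec$ref_levels[[f]])
    if (any(table(df[[f]]) == 0))
      rm_abort("rm_rank_error",
               "factor %s has an empty level (%s) after subsetting", f,
               paste(levels(df[[f]])[table(df[[f]]) == 0], collapse = ","))
  }
  X <- stats::model.matrix(~ condition * treatment * testing_time + site,
                           data = df)
  y <- df[[spec$response]]
  birds <- sort(unique(c(members$bird_a, members$bird_b)))
  pairs <- sort(unique(members$pair_id))
  Z1 <- matrix(0, nrow(df), length(birds), dimnames = list(NULL, birds))
  Z2 <- matrix(0, nrow(df), length(pairs), dimnames = list(NULL, pairs))
  mrow <- match(df$pair_id, members$pair_id)
  for (i in seq_len(nrow(df))) {
    if (df$condition[i] == "paired") {
      Z1[i, members$bird_a[mrow[i]]] <- spec$paired_weight
      Z1[i, members$bird_b[mrow[i]]] <- spec$paired_weight
    } else {
      Z1[i, df$bird_id[i]] <- 1
    }
    Z2[i, df$pair_id[i]] <- 1
  }
  list(y = y, X = X, Z_individual = Z1, Z_pair = Z2, data = df)
}

# Evaluate -2 * REML log-likelihood (profiled over sigma2) and the GLS
# solution at variance ratios `gam` (one per random component; 0 allowed).
# `cp` holds precomputed cross-products.
.reml_eval <- function(gam, cp) {
  n <- cp$n; p <- cp$p
  d <- rep(gam, cp$q_sizes)
  act <- d > 0
  if (any(act)) {
    sd_act <- sqrt(d[act])
    M <- diag(sum(act)) + (sd_act %o% sd_act) * cp$ZtZ[act, act, drop = FALSE]
    Rm <- chol(M)
    tmp <- sd_act * cp$ZtW[act, , drop = FALSE]   # q_act x (p+1)
    CC <- backsolve(Rm, tmp, transpose = TRUE)
    WtVW <- cp$WtW - crossprod(CC)
    logdetM <- 2 * sum(log(diag(Rm)))
  } else {
    WtVW <- cp$WtW
    logdetM <- 0
  }
  XtVX <- WtVW[1:p, 1:p, drop = FALSE]
  XtVy <- WtVW[1:p, p + 1]
  ytVy <- WtVW[p + 1, p + 1]
  Rx <- chol(XtVX)
  beta <- backsolve(Rx, backsolve(Rx, XtVy, transpose = TRUE))
  qres <- max(ytVy - sum(XtVy * beta), 1e-300)
  sigma2 <- qres / (n - p)
  neg2 <- (n - p) * (log(2 * pi) + 1 + log(sigma2)) +
    logdetM + 2 * sum(log(diag(Rx)))
  list(neg2 = neg2, beta = beta, sigma2 = sigma2, Rx = Rx)
}

#' Fit the multimember mixed model by REML
#'
#' Maximises the REML criterion of the variance components over the
#' ratios to the residual variance, on the log scale, with the residual
#' variance profiled out. Optimisation uses Nelder-Mead from three fixed
#' dispersed starts, and every boundary sub-model (each subset of
#' components pinned at zero) is optimised as well; the best criterion
#' value wins, so singular fits are reported as boundary fits rather than
#' errors.
#'
#' @param y response vector.
#' @param X fixed-effects design matrix (full column rank).
#' @param Zs named list of random-effect loading matrices (e.g.
#'   `individual`, `pair`); each row of a membership matrix holds the
#'   weights of that observation on the component's units.
#' @param reltol relative convergence tolerance of the optimiser.
#' @return object of class `mm_fit`: `beta`, `se`, `vcov`, `sigma2_resid`,
#'   per-component variances (`sigma2_<name>`), `loglik_reml`, `n_obs`,
#'   `convergence`, and the design (for refits and diagnostics).
#' @export
fit_reml <- function(y, X, Zs, reltol = 1e-12) {
  n <- length(y); p <- ncol(X)
  if (n <= p)
    rm_abort("rm_rank_error", "need more observations (%d) than columns (%d)",
             n, p)
  if (qr(X)$rank < p)
    rm_abort("rm_rank_error", "fixed-effects design is rank deficient")
  k <- length(Zs)
  Z <- do.call(cbind, Zs)
  W <- cbind(X, y)
  cp <- list(n = n, p = p, q_sizes = vapply(Zs, ncol, 1L),
             ZtZ = crossprod(Z), ZtW = crossprod(Z, W), WtW = crossprod(W))
  best <- NULL; best_gam <- NULL; convergence <- TRUE
  consider <- function(gam, conv = TRUE) {
    ev <- .reml_eval(gam, cp)
    if (is.null(best) || ev$neg2 < best$neg2 - 1e-12) {
      best <<- ev; best_gam <<- gam
      if (!conv) convergence <<- FALSE
    }
  }
  subsets <- expand.grid(rep(list(c(FALSE, TRUE)), k))
  for (s in seq_len(nrow(subsets))) {
    act <- as.logical(subsets[s, ])
    if (!any(act)) { consider(rep(0, k)); next }
    obj <- function(eta) {
      gam <- rep(0, k); gam[act] <- exp(eta)
      .reml_eval(gam, cp)$neg2
    }
    if (sum(act) == 1) {
      op <- stats::optimize(obj, c(-20, 12), tol = 1e-10)
      gam <- rep(0, k); gam[act] <- exp(op$minimum)
      consider(gam)
    } else {
      for (start in list(rep(-2, sum(act)), rep(0, sum(act)),
                         rep(2, sum(act)))) {
        op <- stats::optim(start, obj, method = "Nelder-Mead",
                           control = list(reltol = reltol, maxit = 1000))
        gam <- rep(0, k); gam[act] <- exp(op$par)
        consider(gam, conv = op$convergence == 0)
      }
    }
  }
  gam <- ifelse(best_gam < 1e-10, 0, best_gam)  # snap to the boundary
  ev <- .reml_eval(gam, cp)
  Rx_inv <- backsolve(ev$Rx, diag(p))
  vcov <- ev$sigma2 * tcrossprod(Rx_inv)
  dimnames(vcov) <- list(colnames(X), colnames(X))
  comp <- gam * ev$sigma2
  names(comp) <- paste0("sigma2_", names(Zs))
  fit <- c(list(beta = stats::setNames(drop(ev$beta), colnames(X)),
                se = sqrt(diag(vcov)), vcov = vcov,
                sigma2_resid = ev$sigma2, gamma = gam,
                loglik_reml = -ev$neg2 / 2, n_obs = n,
                convergence = convergence,
                boundary = any(gam == 0),
                y = y, X = X, Zs = Zs),
           as.list(comp))
  class(fit) <- "mm_fit"
  fit
}

#' @export
print.mm_fit <- function(x, ...) {
  cat(sprintf("Multimember mixed model (REML), %d obs, logLik %.3f%s\n",
              x$n_obs, x$loglik_reml,
              if (x$boundary) " [boundary]" else ""))
  comp <- x[grep("^sigma2_", names(x))]
  cat("Variance components:\n")
  for (nm in names(comp)) cat(sprintf("  %-18s %.5g\n", nm, comp[[nm]]))
  cat("Fixed effects:\n")
  print(round(cbind(estimate = x$beta, se = x$se,
                    t = x$beta / x$se), 4))
  invisible(x)
}

#' Wald tests for all fixed effects
#'
#' Per coefficient: t = estimate / SE, with a two-sided p-value from the
#' standard normal reference (no denominator-df correction, matching the
#' reporting convention of Wald tests from model estimates and standard
#' errors).
#'
#' @param fit an [fit_reml()] result.
#' @return data.frame: `term`, `estimate`, `se`, `t_value`, `p_value`.
#' @export
wald_tests <- function(fit) {
  t_value <- fit$beta / fit$se
  data.frame(term = names(fit$beta), estimate = unname(fit$beta),
             se = unname(fit$se), t_value = unname(t_value),
             p_value = unname(2 * stats::pnorm(-abs(t_value))),
             row.names = NULL)
}

#' Linear-combination Wald result from a fitted model
#' @param fit an [fit_reml()] result.
#' @param cvec contrast vector (length = number of coefficients).
#' @return one-row data.frame as in [wald_tests()].
#' @export
contrast_estimate <- function(fit, cvec) {
  est <- sum(cvec * fit$beta)
  se <- sqrt(drop(t(cvec) %*% fit$vcov %*% cvec))
  data.frame(term = "contrast", estimate = est, se = se,
             t_value = est / se, p_value = 2 * stats::pnorm(-abs(est / se)))
}

#' Planned contrast by releveling
#'
#' Refits the identical model with new reference levels so that a simple
#' effect of interest becomes a first-order coefficient, and returns its
#' Wald row. Releveling only reparameterises the fixed effects: the REML
#' log-likelihood is unchanged.
#'
#' @param rows metric table.
#' @param spec a [model_spec()].
#' @param members pair membership lookup.
#' @param ref_levels named list of reference levels to switch to (others
#'   kept from `spec`).
#' @param term coefficient name to report, e.g. `"conditionsolo"`.
#' @return one-row data.frame as in [wald_tests()], with the fit attached
#'   as attribute `"fit"`.
#' @export
planned_contrast <- function(rows, spec, members, ref_levels,
                             term = "conditionsolo") {
  spec2 <- spec
  spec2$ref_levels[names(ref_levels)] <- ref_levels
  des <- build_design(rows, spec2, members)
  fit <- fit_reml(des$y, des$X, list(individual = des$Z_individual,
                                     pair = des$Z_pair))
  wt <- wald_tests(fit)
  out <- wt[wt$term == term, , drop = FALSE]
  if (nrow(out) == 0)
    rm_abort("rm_domain_error", "no coefficient named %s; have: %s", term,
             paste(wt$term, collapse = ", "))
  rownames(out) <- NULL
  attr(out, "fit") <- fit
  out
}

#' Residual diagnostics of a fitted model
#'
#' Whitens the marginal residuals with the Cholesky factor of the fitted
#' covariance (so they are iid standard normal under the model), applies
#' the one-sample Kolmogorov-Smirnov test against N(0, 1), and returns the
#' QQ pairs for plotting. The KS test ignores that the parameters were
#' estimated, as is common practice; treat borderline p-values with care.
#'
#' @param fit an [fit_reml()] result.
#' @return list: `ks_statistic`, `ks_p`, `qq` (data.frame `theoretical`,
#'   `empirical`, both sorted), `residuals`.
#' @export
residual_diagnostics <- function(fit) {
  n <- fit$n_obs
  V0 <- diag(n)
  for (i in seq_along(fit$Zs))
    V0 <- V0 + fit$gamma[i] * tcrossprod(fit$Zs[[i]])
  L <- t(chol(fit$sigma2_resid * V0))
  r <- fit$y - drop(fit$X %*% fit$beta)
  w <- drop(forwardsolve(L, r))
  ks <- suppressWarnings(stats::ks.test(w, "pnorm"))
  list(ks_statistic = unname(ks$statistic), ks_p = ks$p.value,
       qq = data.frame(theoretical = stats::qnorm(stats::ppoints(n)),
                       empirical = sort(w)),
       residuals = w)
}

#' Reduce a metric table to pairs vs the better solo bird of each pair
#'
#' For every pair whose two members were both tested solo (at a given
#' testing time and solo-release round), keeps only the member with the
#' smaller route-memory metric; paired-condition rows are kept as they
#' are. The selection is made independently per metric, so the better bird
#' may differ between the mean NND and the 2nd-order mean NND. Pairs with
#' only one solo member at a round are excluded from the comparison and
#' listed in the attached log.
#'
#' @param rows metric table.
#' @param metric raw metric column used for the "better" selection
#'   (`"mean_nnd_m"` or `"so_mean_nnd_m"`).
#' @return reduced metric table (attribute `"dropped"` lists exclusions).
#' @export
better_solo_comparison <- function(rows, metric = "mean_nnd_m") {
  solo <- rows[rows$condition == "solo" & !is.na(rows[[metric]]), ]
  keep_ids <- character(0); dropped <- character(0)
  grp <- split(solo, list(solo$pair_id, solo$site, solo$testing_time),
               drop = TRUE)
  for (g in grp) {
    g <- g[order(g$release_order), ]
    # per-bird round index: k-th solo release of that bird in this cell
    g$round <- stats::ave(seq_len(nrow(g)), g$bird_id, FUN = seq_along)
    for (rd in unique(g$round)) {
      sub <- g[g$round == rd, ]
      if (length(unique(sub$bird_id)) == 2) {
        keep_ids <- c(keep_ids, sub$release_id[which.min(sub[[metric]])])
      } else {
        dropped <- c(dropped,
                     sprintf("%s/%s/%s round %d: only one solo member",
                             sub$pair_id[1], sub$site[1],
                             sub$testing_time[1], rd))
      }
    }
  }
  out <- rows[rows$condition == "paired" |
                (rows$condition == "solo" & rows$release_id %in% keep_ids), ]
  rownames(out) <- NULL
  attr(out, "dropped") <- dropped
  out
}
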