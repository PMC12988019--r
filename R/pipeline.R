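# End-to-end orchestration: simulate (or load) -> preprocess -> metrics ->
# mixed models -> planned contrasts -> diagnostics, with every artifact
# written as CSV when an output directory is given. Also the replicated
# simulation studies (type-I calibration and effect recovery) used for
# validating the inference machinery.

.default_responses <- c(mean_nnd = "log_mean_nnd",
                        so_mean_nnd = "log_so_mean_nnd",
                        hei = "hei_transformed")

#' Summarise every reported comparison from a metric table
#'
#' Fits the factorial multimember model per response and reads off the
#' planned contrasts by releveling: pair vs solo at memory testing and at
#' baseline within each treatment, the testing-time x condition
#' interaction within each treatment, the baseline-to-memory efficiency
#' change per condition and treatment, and pair vs the better solo member
#' (route-memory metrics, memory testing, per treatment).
#'
#' @param metric_table output of [build_metric_table()].
#' @param members pair membership lookup (see [pair_members()]).
#' @param responses named character vector of response columns.
#' @return data.frame: comparison, response, treatment, estimate, se, t, p.
#' @export
summarize_contrasts <- function(metric_table, members,
                                responses = .default_responses) {
  out <- list()
  grab <- function(comparison, response, treatment, rows, refs, term) {
    res <- tryCatch(
      planned_contrast(rows, model_spec(response), members, refs, term),
      routemem_error = function(e) {
        warning(sprintf("contrast %s / %s: %s", comparison, response,
                        conditionMessage(e)), call. = FALSE)
        NULL
      })
    if (!is.null(res))
      out[[length(out) + 1]] <<- data.frame(
        comparison = comparison, response = response, treatment = treatment,
        estimate = res$estimate, se = res$se, t_value = res$t_value,
        p_value = res$p_value)
  }
  for (tr in c("forgetting", "extra_training")) {
    for (resp in responses) {
      grab("pair_vs_solo_memory", resp, tr, metric_table,
           list(treatment = tr, testing_time = "memory_testing",
                condition = "paired"), "conditionsolo")
      grab("pair_vs_solo_baseline", resp, tr, metric_table,
           list(treatment = tr, testing_time = "baseline",
                condition = "paired"), "conditionsolo")
      grab("condition_x_testing_time", resp, tr, metric_table,
           list(treatment = tr, testing_time = "baseline",
                condition = "paired"),
           "conditionsolo:testing_timememory_testing")
    }
    for (metric in c(mean_nnd = "mean_nnd_m", so_mean_nnd = "so_mean_nnd_m")) {
      resp <- .default_responses[[sub("_m$", "", sub("so_mean_nnd_m",
                                                     "so_mean_nnd", metric))]]
      resp <- if (metric == "mean_nnd_m") "log_mean_nnd" else "log_so_mean_nnd"
      reduced <- better_solo_comparison(metric_table, metric)
      grab("pair_vs_better_solo_memory", resp, tr, reduced,
           list(treatment = tr, testing_time = "memory_testing",
                condition = "paired"), "conditionsolo")
    }
    for (cond in c("paired", "solo"))
      grab(sprintf("efficiency_drop_%s", cond), "hei_transformed", tr,
           metric_table,
           list(treatment = tr, condition = cond, testing_time = "baseline"),
           "testing_timememory_testing")
  }
  do.call(rbind, out)
}

#' Run the full analysis pipeline
#'
#' Simulates an experiment (or takes one already generated/loaded),
#' preprocesses all tracks, builds the metric table, fits the three
#' factorial multimember models, extracts every planned contrast and the
#' residual diagnostics, and optionally writes all artifacts (exclusion
#' ledger, metric CSV, contrast CSV, QQ data, summary text) to a
#' directory. Deterministic given the configuration seed.
#'
#' @param config a [sim_config()]; ignored if `experiment` is supplied.
#' @param experiment optional result of [generate_experiment()] (or a list
#'   with `tracks`, `metadata` read from disk).
#' @param params a [preprocess_params()].
#' @param out_dir optional output directory.
#' @param check_joining run the joined-flight scan (quadratic in tracks).
#' @return list: `experiment`, `preprocessed`, `metric_table`, `fits`,
#'   `contrasts`, `diagnostics`, `summary` (character).
#' @export
run_pipeline <- function(config = sim_config(), experiment = NULL,
                         params = preprocess_params(), out_dir = NULL,
                         check_joining = TRUE) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      rm_abort("rm_pipeline_error", "[stage %s] %s", name,
               conditionMessage(e))
    })
  }
  if (is.null(experiment))
    experiment <- stage("simulate", generate_experiment(config))
  sites <- if (!is.null(experiment$config)) experiment$config$sites
           else config$sites
  prep <- stage("preprocess",
                preprocess_experiment(experiment$tracks, experiment$metadata,
                                      sites, params,
                                      check_joining = check_joining))
  metric_table <- stage("metrics",
                        build_metric_table(prep$tracks, experiment$metadata))
  members <- pair_members(experiment$metadata)
  fits <- list(); diagnostics <- list()
  for (nm in names(.default_responses)) {
    resp <- .default_responses[[nm]]
    des <- stage("fit", build_design(metric_table, model_spec(resp), members))
    fits[[resp]] <- stage("fit", fit_reml(des$y, des$X,
                                          list(individual = des$Z_individual,
                                               pair = des$Z_pair)))
    diagnostics[[resp]] <- stage("diagnostics",
                                 residual_diagnostics(fits[[resp]]))
  }
  contrasts <- stage("contrasts", summarize_contrasts(metric_table, members))
  summary_txt <- c(
    sprintf("routemem pipeline: %d tracks in, %d excluded/truncated entries, %d metric rows",
            length(experiment$tracks), nrow(prep$exclusions),
            nrow(metric_table)),
    sprintf("KS residual normality p: %s",
            paste(sprintf("%s=%.3f", names(diagnostics),
                          vapply(diagnostics, `[[`, 0, "ks_p")),
                  collapse = ", ")),
    utils::capture.output(print(contrasts, digits = 3)))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(metric_table, file.path(out_dir, "metric_table.csv"),
                     row.names = FALSE)
    utils::write.csv(prep$exclusions, file.path(out_dir, "exclusions.csv"),
                     row.names = FALSE)
    utils::write.csv(contrasts, file.path(out_dir, "contrasts.csv"),
                     row.names = FALSE)
    qq <- do.call(rbind, lapply(names(diagnostics), function(r)
      cbind(response = r, diagnostics[[r]]$qq)))
    utils::write.csv(qq, file.path(out_dir, "qq_points.csv"),
                     row.names = FALSE)
    writeLines(summary_txt, file.path(out_dir, "summary.txt"))
  }
  list(experiment = experiment, preprocessed = prep,
       metric_table = metric_table, fits = fits, contrasts = contrasts,
       diagnostics = diagnostics, summary = summary_txt)
}

#' Configuration for replicated simulation studies
#'
#' The replicated calibration and recovery studies run many simulated
#' experiments, so they use an 8 s GPS sampling interval (145 m fix
#' spacing, still dense relative to the 400-800 m corridor scales) and
#' shortened dawdle/approach phases; all thresholds and physical scales
#' are unchanged, and the quadratic joined-flight scan is skipped because
#' the generator's release spacing keeps flight windows disjoint. All
#' other knobs keep the study defaults.
#'
#' @param seed integer seed.
#' @param ... overrides passed on to [sim_config()].
#' @export
replication_config <- function(seed = 1, ...) {
  sim_config(sample_interval_s = 8, dawdle_s = 16, approach_s = 16,
             seed = seed, ...)
}

#' Replicated planned-contrast study
#'
#' Runs `n_rep` independent synthetic experiments (seeds `seed + 1:n_rep`)
#' and, for each, fits the releveled multimember model and records the
#' pair-vs-solo simple effect at memory testing in the forgetting
#' treatment together with the condition x testing-time interaction.
#' With `null = TRUE` retention is set to 1 in both treatments (no
#' forgetting), the null generator used for type-I calibration.
#'
#' @param n_rep number of replicate experiments.
#' @param seed base seed.
#' @param null simulate under the no-forgetting null.
#' @param response response column.
#' @param config_fn function(seed, ...) building the per-replicate
#'   [sim_config()]; defaults to [replication_config()].
#' @return data.frame with one row per replicate: estimate, se, t and p of
#'   the condition contrast, and of the interaction.
#' @export
contrast_replicates <- function(n_rep, seed = 1, null = FALSE,
                                response = "log_mean_nnd",
                                config_fn = replication_config) {
  res <- vector("list", n_rep)
  for (r in seq_len(n_rep)) {
    cfg <- if (null)
      config_fn(seed = seed + r, retention_forgetting = 1, retention_extra = 1)
    else config_fn(seed = seed + r)
    exp_ <- generate_experiment(cfg)
    prep <- preprocess_experiment(exp_$tracks, exp_$metadata, cfg$sites,
                                  check_joining = FALSE)
    tab <- build_metric_table(prep$tracks, exp_$metadata,
                              second_order = response == "log_so_mean_nnd")
    members <- pair_members(exp_$metadata)
    cc <- planned_contrast(tab, model_spec(response), members,
                           list(treatment = "forgetting",
                                testing_time = "memory_testing",
                                condition = "paired"), "conditionsolo")
    fit <- attr(cc, "fit")
    wt <- wald_tests(fit)
    # under the releveled fit the interaction is coded against the
    # memory-testing reference; flip the sign so it reads
    # (solo - pair at memory) - (solo - pair at baseline)
    ia <- wt[grepl("^conditionsolo:testing_time", wt$term), ]
    if (grepl("baseline$", ia$term[1])) {
      ia$estimate <- -ia$estimate
      ia$t_value <- -ia$t_value
    }
    res[[r]] <- data.frame(replicate = r, estimate = cc$estimate, se = cc$se,
                           t_value = cc$t_value, p_value = cc$p_value,
                           ia_estimate = ia$estimate, ia_se = ia$se,
                           ia_t_value = ia$t_value, ia_p_value = ia$p_value)
  }
  do.call(rbind, res)
}
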