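#' Frozen generative agents for the stimulus-action validation example
#'
#' Reads the packaged configuration of the two artificial agents used in
#' the validation demonstration: a stimulus-blind learner with low choice
#' noise and a state-based learner with high choice noise, on the
#' deterministic 3-stimulus / 3-action task. Their parameters were tuned
#' once so that the two agents' session-average learning curves are
#' approximately equal, and are kept frozen in
#' `inst/extdata/validation_agents.json`.
#'
#' @return A list with `blind` and `state` [param_set()]s, `n_trials`, and
#'   `n_agents` used by the canned experiment.
#' @export
validation_agents <- function() {
  path <- system.file("extdata", "validation_agents.json", package = "banditfit")
  cfg <- jsonlite::fromJSON(path)
  list(
    blind = param_set("blindRL", alpha = cfg$blind$alpha,
                      beta = cfg$blind$beta),
    state = param_set("stateRL", alpha = cfg$state$alpha,
                      beta = cfg$state$beta),
    n_trials = cfg$n_trials,
    n_agents = cfg$n_agents
  )
}

#' Configuration for a canned experiment
#'
#' @param name One of `"signatures"`, `"param-recovery"`,
#'   `"model-recovery-noisy"`, `"model-recovery-lownoise"`,
#'   `"nuisance-bias"`, `"validation-example"` — the workbench's canned
#'   protocols: model-signature
#'   simulation sweeps, parameter recovery, model recovery under noisy and
#'   low-noise priors, the nuisance-bias recovery comparison, and the
#'   stimulus-learning validation example.
#' @param out_dir Output directory (created if needed).
#' @param seed Master seed; all stage seeds derive from it.
#' @param n_reps,n_starts,n_trials Optional overrides of the protocol
#'   defaults.
#' @return A list of class `experiment_config`.
#' @export
experiment_config <- function(name, out_dir = ".", seed = 1L,
                              n_reps = NULL, n_starts = NULL,
                              n_trials = NULL) {
  known <- c("signatures", "param-recovery", "model-recovery-noisy",
             "model-recovery-lownoise", "nuisance-bias",
             "validation-example")
  if (!name %in% known) {
    stop("unknown experiment '", name, "'; choose one of: ",
         paste(known, collapse = ", "), call. = FALSE)
  }
  structure(list(name = name, out_dir = out_dir, seed = as.integer(seed),
                 n_reps = n_reps, n_starts = n_starts, n_trials = n_trials),
            class = "experiment_config")
}

write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Run a canned experiment end-to-end
#'
#' Executes the named protocol with the package defaults (overridable via
#' the config), writes its CSV/JSON artifacts into the configured output
#' directory, and drops a `manifest.json` (config, resolved seeds,
#' package version) next to them so every output can be regenerated.
#'
#' @param config An [experiment_config()].
#' @return Named character vector of the files written, invisibly.
#' @export
run_experiment <- function(config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed
  files <- switch(config$name,
    "signatures" = run_signatures(config),
    "param-recovery" = run_param_recovery(config),
    "model-recovery-noisy" = run_model_recovery_exp(config, panel = "A"),
    "model-recovery-lownoise" = run_model_recovery_exp(config, panel = "B"),
    "nuisance-bias" = run_nuisance_bias(config),
    "validation-example" = run_validation_exp(config)
  )
  manifest <- list(
    experiment = config$name, seed = seed,
    n_reps = config$n_reps, n_starts = config$n_starts,
    n_trials = config$n_trials,
    package_version = as.character(utils::packageVersion("banditfit")),
    files = as.list(files)
  )
  mpath <- file.path(config$out_dir, paste0(config$name, "_manifest.json"))
  write_json_file(manifest, mpath)
  invisible(c(files, manifest = mpath))
}

signature_example_params <- function() {
  list(M1 = param_set("M1", b = 0.5),
       M2 = param_set("M2", epsilon = 0.05),
       M3 = param_set("M3", alpha = 0.1, beta = 5),
       M4 = param_set("M4", alpha_c = 0.1, beta_c = 3),
       M5 = param_set("M5", alpha = 0.1, beta = 5, alpha_c = 0.1,
                      beta_c = 1))
}

run_signatures <- function(config) {
  n_sims <- config$n_reps %||% 100L
  T_n <- config$n_trials %||% 1000L
  task <- bandit_task(2, T_n, c(0.2, 0.8))
  params <- signature_example_params()
  rows <- do.call(rbind, lapply(names(params), function(m) {
    sims <- lapply(seq_len(n_sims), function(i) {
      simulate_agent(params[[m]], task,
                     seed = (config$seed * 1000L + i) %% 2147483647L)
    })
    sp <- t(vapply(sims, function(d) suppressWarnings(stay_probability(d)),
                   numeric(2)))
    pc <- performance_curves(sims, task)
    data.frame(model = m,
               stay_win = mean(sp[, "stay_win"], na.rm = TRUE),
               stay_lose = mean(sp[, "stay_lose"], na.rm = TRUE),
               perf_early = pc$perf_early, perf_late = pc$perf_late)
  }))
  path <- file.path(config$out_dir, "signature_measures.csv")
  write.csv(rows, path, row.names = FALSE)
  c(measures = path)
}

run_param_recovery <- function(config) {
  rep_n <- config$n_reps %||% 1000L
  T_n <- config$n_trials %||% 1000L
  opts <- fit_options(n_starts = config$n_starts %||% 10L)
  report <- recover_parameters(
    "M3", priors = list(alpha = prior_unif(), beta = prior_exp(10)),
    n_reps = rep_n, task = bandit_task(2, T_n, c(0.2, 0.8)),
    options = opts, seed = config$seed)
  scatter <- file.path(config$out_dir, "param_recovery_scatter.csv")
  write_recovery_csv(report, scatter, threshold = 0.25)
  summ <- file.path(config$out_dir, "param_recovery_summary.json")
  write_json_file(list(summary = report$summary, n_failed = report$n_failed),
                  summ)
  c(scatter = scatter, summary = summ)
}

run_model_recovery_exp <- function(config, panel) {
  rep_n <- config$n_reps %||% 100L
  T_n <- config$n_trials %||% 1000L
  models <- c("M1", "M2", "M3", "M4", "M5")
  priors <- setNames(lapply(models, recovery_priors, panel = panel), models)
  cm <- model_recovery(models, priors, n_reps = rep_n,
                       task = bandit_task(2, T_n, c(0.2, 0.8)),
                       options = fit_options(n_starts = config$n_starts %||% 10L),
                       seed = config$seed)
  inv <- invert_confusion(cm)
  tag <- if (panel == "A") "noisy" else "lownoise"
  cpath <- file.path(config$out_dir,
                     paste0("model_recovery_", tag, "_confusion.csv"))
  ipath <- file.path(config$out_dir,
                     paste0("model_recovery_", tag, "_inversion.csv"))
  write_matrix_csv(cm, cpath)
  write_matrix_csv(inv, ipath)
  c(confusion = cpath, inversion = ipath)
}

run_nuisance_bias <- function(config) {
  rep_n <- config$n_reps %||% 100L
  res <- compare_nested_recovery(
    "M3bias", "M3",
    priors = list(alpha = prior_unif(), beta = prior_exp(1, shift = 1),
                  bias = prior_unif(-1, 1)),
    n_reps = rep_n,
    options = fit_options(n_starts = config$n_starts %||% 10L),
    seed = config$seed)
  spath <- file.path(config$out_dir, "nuisance_bias_summary.csv")
  write.csv(res$summary, spath, row.names = FALSE)
  rpath <- file.path(config$out_dir, "nuisance_bias_replicates.csv")
  merged <- merge(res$replicates_full, res$replicates_reduced,
                  by = "replicate", suffixes = c("_full", "_reduced"))
  write.csv(merged, rpath, row.names = FALSE)
  c(summary = spath, replicates = rpath)
}

#' Simulate the validation example and fit the state-based model
#'
#' Internal engine shared by the canned experiment and the acceptance
#' checks: simulates `n_agents` sessions from each frozen agent, fits the
#' state-based model to every session, and reports the fitted
#' geometric-mean trial likelihoods plus posterior predictive learning
#' curves at the mean fitted parameters.
#'
#' @param seed Master seed.
#' @param n_agents,n_trials Optional overrides of the frozen defaults.
#' @param n_starts Multistart count for the fits.
#' @return A list with per-agent-type fitted likelihoods, observed and
#'   posterior-predictive learning curves, and the fitted parameter sets.
#' @export
run_validation_example <- function(seed = 1L, n_agents = NULL,
                                   n_trials = NULL, n_starts = 5L) {
  agents <- validation_agents()
  n_agents <- n_agents %||% agents$n_agents
  n_trials <- n_trials %||% agents$n_trials
  task <- stimulus_task(n_trials, schedule_seed = seed)
  opts <- fit_options(n_starts = n_starts)
  one_side <- function(gen_params, label) {
    sims <- lapply(seq_len(n_agents), function(i) {
      simulate_agent(gen_params, task,
                     seed = (seed * 1000L + i * 31L) %% 2147483647L,
                     agent_id = paste0(label, i))
    })
    fits <- lapply(seq_along(sims), function(i) {
      fit_mle("stateRL", sims[[i]],
              within_options(opts, seed * 1000L + i * 37L))
    })
    geo <- vapply(seq_along(sims), function(i) {
      average_trial_likelihood(fits[[i]]$best_params, sims[[i]])[["geometric"]]
    }, numeric(1))
    mean_par <- colMeans(do.call(rbind, lapply(fits, function(f) {
      f$best_params$values
    })))
    fitted_ps <- param_set("stateRL", alpha = mean_par[["alpha"]],
                           beta = mean_par[["beta"]])
    obs_curve <- performance_curves(sims, task)$learning_curve
    ppc <- posterior_predictive(fitted_ps, task, n_sims = n_agents,
                                seed = seed + 5L)
    list(geometric = geo, observed_curve = obs_curve,
         predicted_curve = ppc$learning_curve, fitted = fitted_ps,
         sims = sims)
  }
  list(blind = one_side(agents$blind, "blind"),
       state = one_side(agents$state, "state"),
       task = task)
}

run_validation_exp <- function(config) {
  res <- run_validation_example(seed = config$seed,
                                n_agents = config$n_reps,
                                n_trials = config$n_trials,
                                n_starts = config$n_starts %||% 5L)
  summ <- list(
    geometric_likelihood = list(
      state_fit_on_blind = mean(res$blind$geometric),
      state_fit_on_state = mean(res$state$geometric)
    ),
    fitted_params = list(
      on_blind = as.list(res$blind$fitted$values),
      on_state = as.list(res$state$fitted$values)
    )
  )
  spath <- file.path(config$out_dir, "validation_example_summary.json")
  write_json_file(summ, spath)
  curves <- data.frame(
    trial = seq_along(res$blind$observed_curve),
    blind_observed = res$blind$observed_curve,
    blind_predicted = res$blind$predicted_curve,
    state_observed = res$state$observed_curve,
    state_predicted = res$state$predicted_curve
  )
  cpath <- file.path(config$out_dir, "validation_example_curves.csv")
  write.csv(curves, cpath, row.names = FALSE)
  c(summary = spath, curves = cpath)
}
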