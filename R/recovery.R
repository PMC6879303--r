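#' Parameter-recovery experiment
#'
#' The central audit of identifiability: repeatedly draw "true" parameters
#' from priors, simulate a session, refit by maximum likelihood, and
#' compare simulated to recovered values. Reports per-parameter Pearson
#' and Spearman correlations and mean signed bias (fit minus simulated),
#' plus the correlations AMONG the fitted parameters — a diagnostic for
#' parameters trading off against each other even when the generating
#' draws were independent.
#'
#' @param model_id Model to simulate and refit.
#' @param priors Prior list as accepted by [sample_parameters()].
#' @param n_reps Number of replicates (>= 2).
#' @param task Task the agents perform.
#' @param options A [fit_options()].
#' @param seed Master seed; per-replicate seeds derive from it.
#' @param q0 Initial option value used for both simulation and fitting.
#' @param reset_blocks Reset learner state per block (simulation and fit).
#' @return A list of class `recovery_report`: `replicates` (data frame
#'   with `sim_<param>`, `fit_<param>`, `loglik`), `summary` (per-parameter
#'   `pearson`, `spearman`, `bias`), `fit_cor` (correlation matrix of
#'   fitted parameters), `n_failed`.
#' @export
recover_parameters <- function(model_id, priors = default_priors(model_id),
                               n_reps = 1000L,
                               task = bandit_task(2, 1000, c(0.2, 0.8)),
                               options = fit_options(), seed = 1L,
                               q0 = 0, reset_blocks = TRUE) {
  if (n_reps < 2L) stop("n_reps must be >= 2", call. = FALSE)
  info <- model_info(model_id)
  pn <- info$params
  rows <- vector("list", n_reps)
  n_failed <- 0L
  options$q0 <- q0
  options$reset_blocks <- reset_blocks
  for (rep in seq_len(n_reps)) {
    rep_seed <- (seed * 1000L + rep * 13L) %% 2147483647L
    set.seed(rep_seed)
    theta <- sample_parameters(model_id, priors, q0 = q0)
    data <- simulate_agent(theta, task, seed = rep_seed + 1L,
                           reset_blocks = reset_blocks)
    fit <- tryCatch(
      fit_mle(model_id, data, within_options(options, rep_seed + 2L)),
      error = function(e) NULL
    )
    if (is.null(fit)) {
      n_failed <- n_failed + 1L
      next
    }
    row <- data.frame(replicate = rep)
    for (nm in pn) row[[paste0("sim_", nm)]] <- theta$values[[nm]]
    for (nm in pn) row[[paste0("fit_", nm)]] <- fit$best_params$values[[nm]]
    row$loglik <- fit$best_loglik
    rows[[rep]] <- row
  }
  reps <- do.call(rbind, rows)
  summary <- do.call(rbind, lapply(pn, function(nm) {
    s <- reps[[paste0("sim_", nm)]]; f <- reps[[paste0("fit_", nm)]]
    pe <- if (sd(s) > 0 && sd(f) > 0) cor(s, f) else NA_real_
    sp <- if (sd(s) > 0 && sd(f) > 0) cor(s, f, method = "spearman") else NA_real_
    data.frame(param = nm, pearson = pe, spearman = sp, bias = mean(f - s))
  }))
  fit_cor <- if (length(pn) > 1L) {
    stats::cor(as.matrix(reps[, paste0("fit_", pn)]))
  } else NULL
  structure(list(model_id = model_id, replicates = reps, summary = summary,
                 fit_cor = fit_cor, n_failed = n_failed, n_reps = n_reps),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("<recovery_report>", x$model_id, "-", nrow(x$replicates),
      "replicates")
  if (x$n_failed) cat(" (", x$n_failed, "failed )")
  cat("\n")
  print(transform(x$summary, pearson = round(pearson, 3),
                  spearman = round(spearman, 3), bias = round(bias, 3)),
        row.names = FALSE)
  invisible(x)
}

#' Flag replicates with poor recovery of one parameter
#'
#' @param report A [recover_parameters()] report.
#' @param parameter Parameter name.
#' @param threshold Absolute simulated-vs-fitted discrepancy above which a
#'   replicate is flagged (e.g. 0.25 for a learning rate).
#' @return Integer vector of flagged replicate ids.
#' @export
flag_poor_recovery <- function(report, parameter, threshold) {
  reps <- report$replicates
  s <- reps[[paste0("sim_", parameter)]]
  f <- reps[[paste0("fit_", parameter)]]
  if (is.null(s)) stop("unknown parameter '", parameter, "'", call. = FALSE)
  reps$replicate[abs(s - f) > threshold]
}

#' Write a recovery scatter table to CSV
#'
#' Long format: one row per (replicate, parameter) with the simulated and
#' fitted value and a flag column (using `threshold` on the absolute
#' discrepancy).
#'
#' @param report A [recover_parameters()] report.
#' @param path Output path.
#' @param threshold Discrepancy threshold used for the `flagged` column.
#' @return `path`, invisibly.
#' @export
write_recovery_csv <- function(report, path, threshold = 0.25) {
  pn <- model_info(report$model_id)$params
  reps <- report$replicates
  long <- do.call(rbind, lapply(pn, function(nm) {
    data.frame(replicate = reps$replicate, param = nm,
               sim = reps[[paste0("sim_", nm)]],
               fit = reps[[paste0("fit_", nm)]])
  }))
  long$flagged <- abs(long$sim - long$fit) > threshold
  write.csv(long, path, row.names = FALSE)
  invisible(path)
}

#' Effect of omitting a nuisance parameter on recovery
#'
#' Simulates from a full model (by default the side-bias learner on a
#' block-reversal bandit with optimistic initial values Q0 = 0.5) and fits
#' every replicate twice: once with the full model and once with a reduced
#' model that omits the nuisance parameter(s). Returns recovery summaries
#' for the parameters the two models share, so one can see how much
#' modeling the "unimportant" parameter improves recovery of the
#' parameters of interest.
#'
#' @param model_full Model whose parameter set is a superset (also the
#'   generating model unless `generating_model` says otherwise).
#' @param model_reduced Nested model omitting the nuisance parameter(s).
#' @param priors Priors for the generating model's parameters.
#' @param n_reps Number of replicates.
#' @param task Task (default: 10 x 50-trial reversal blocks, 0.2/0.8).
#' @param options A [fit_options()].
#' @param seed Master seed.
#' @param q0 Initial option value (default 0.5, unbiased between the
#'   arms).
#' @param generating_model Model to simulate from (default `model_full`).
#' @return A list of class `nested_recovery`: per-fit data frames
#'   `replicates_full`, `replicates_reduced` and a `summary` data frame of
#'   per-shared-parameter Pearson correlations and biases for both fits.
#' @export
compare_nested_recovery <- function(model_full, model_reduced,
                                    priors = default_priors(model_full),
                                    n_reps = 100L,
                                    task = reversal_task(10, 50,
                                      list(c(0.2, 0.8), c(0.8, 0.2))),
                                    options = fit_options(), seed = 1L,
                                    q0 = 0.5,
                                    generating_model = model_full) {
  shared <- intersect(model_info(model_full)$params,
                      model_info(model_reduced)$params)
  if (!setequal(model_info(model_reduced)$params, shared)) {
    stop("model_reduced parameters must nest inside model_full",
         call. = FALSE)
  }
  options$q0 <- q0
  options$reset_blocks <- TRUE
  gen_pn <- model_info(generating_model)$params
  rows_f <- vector("list", n_reps); rows_r <- vector("list", n_reps)
  for (rep in seq_len(n_reps)) {
    rep_seed <- (seed * 1000L + rep * 17L) %% 2147483647L
    set.seed(rep_seed)
    theta <- sample_parameters(generating_model, priors, q0 = q0)
    data <- simulate_agent(theta, task, seed = rep_seed + 1L,
                           reset_blocks = TRUE)
    fit_f <- fit_mle(model_full, data, within_options(options, rep_seed + 2L))
    fit_r <- fit_mle(model_reduced, data, within_options(options, rep_seed + 3L))
    mk <- function(fit, pn) {
      row <- data.frame(replicate = rep)
      for (nm in gen_pn) row[[paste0("sim_", nm)]] <- theta$values[[nm]]
      for (nm in pn) row[[paste0("fit_", nm)]] <- fit$best_params$values[[nm]]
      row$loglik <- fit$best_loglik
      row
    }
    rows_f[[rep]] <- mk(fit_f, model_info(model_full)$params)
    rows_r[[rep]] <- mk(fit_r, shared)
  }
  reps_f <- do.call(rbind, rows_f); reps_r <- do.call(rbind, rows_r)
  summary <- do.call(rbind, lapply(shared, function(nm) {
    s <- reps_f[[paste0("sim_", nm)]]
    data.frame(
      param = nm,
      pearson_full = cor(s, reps_f[[paste0("fit_", nm)]]),
      pearson_reduced = cor(s, reps_r[[paste0("fit_", nm)]]),
      bias_full = mean(reps_f[[paste0("fit_", nm)]] - s),
      bias_reduced = mean(reps_r[[paste0("fit_", nm)]] - s)
    )
  }))
  structure(list(model_full = model_full, model_reduced = model_reduced,
                 replicates_full = reps_f, replicates_reduced = reps_r,
                 summary = summary),
            class = "nested_recovery")
}

#' @export
print.nested_recovery <- function(x, ...) {
  cat("<nested_recovery>", x$model_full, "vs", x$model_reduced, "\n")
  print(transform(x$summary,
                  pearson_full = round(pearson_full, 3),
                  pearson_reduced = round(pearson_reduced, 3),
                  bias_full = round(bias_full, 3),
                  bias_reduced = round(bias_reduced, 3)),
        row.names = FALSE)
  invisible(x)
}
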