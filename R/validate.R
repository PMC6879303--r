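#' Stay probability conditioned on the previous reward
#'
#' The frequency with which the agent repeats its previous choice, split
#' by whether that previous choice was rewarded. A model-independent
#' signature of feedback sensitivity: win-stay-lose-shift agents show a
#' large gap between the two, random responders none. Pairs never straddle
#' a block boundary.
#'
#' @param data A [behav_data()] with at least two trials.
#' @return Named numeric vector `c(stay_win, stay_lose)`; an entry is `NA`
#'   (with a warning) when its conditioning cell is empty.
#' @export
stay_probability <- function(data) {
  if (nrow(data) < 2L) stop("need at least two trials", call. = FALSE)
  same_block <- data$block[-1L] == data$block[-nrow(data)]
  stay <- (data$choice[-1L] == data$choice[-nrow(data)])[same_block]
  prev_r <- data$reward[-nrow(data)][same_block]
  out <- c(stay_win = NA_real_, stay_lose = NA_real_)
  if (any(prev_r == 1L)) out["stay_win"] <- mean(stay[prev_r == 1L])
  if (any(prev_r == 0L)) out["stay_lose"] <- mean(stay[prev_r == 0L])
  if (anyNA(out)) {
    warning("empty conditioning cell; stay probability undefined",
            call. = FALSE)
  }
  out
}

#' Learning curves and early/late performance
#'
#' Per-trial frequency of choosing the correct option (the unique best
#' arm, or the stimulus's rewarded action), averaged across datasets.
#' For multi-block tasks the curve is additionally averaged across blocks
#' of equal length, giving a within-block learning curve.
#'
#' @param datasets A `behav_data` or list of them, all from the same task.
#' @param task The task the data were collected on (defaults to the task
#'   attached to the first dataset).
#' @param window Number of trials in the early/late windows (default 10).
#' @return List with `learning_curve` (per-trial p(correct)),
#'   `perf_early`, `perf_late`, `n_datasets`.
#' @export
performance_curves <- function(datasets, task = NULL, window = 10L) {
  if (inherits(datasets, "behav_data")) datasets <- list(datasets)
  if (is.null(task)) task <- attr(datasets[[1]], "task")
  if (is.null(task)) stop("no task available", call. = FALSE)
  correct <- correct_option(task)
  hits <- vapply(datasets, function(d) {
    as.numeric(d$choice == correct)
  }, numeric(task$n_trials))
  per_trial <- rowMeans(hits)
  starts <- task$block_starts
  if (length(starts) > 1L) {
    lens <- diff(c(starts, task$n_trials + 1L))
    if (length(unique(lens)) == 1L) {
      # fold blocks: within-block learning curve
      per_trial <- rowMeans(matrix(per_trial, nrow = lens[1]))
    }
  }
  n <- length(per_trial)
  w <- min(window, n)
  list(learning_curve = per_trial,
       perf_early = mean(per_trial[seq_len(w)]),
       perf_late = mean(per_trial[seq.int(n - w + 1L, n)]),
       n_datasets = length(datasets))
}

#' Geometric-mean per-trial likelihood
#'
#' `exp(LL / T)`: an absolute measure of fit on the probability scale,
#' 1/K for a chance-level model with K options and 1 only for a perfect
#' predictor. The arithmetic mean of the per-trial likelihoods is returned
#' alongside for reference.
#'
#' @inheritParams negative_log_likelihood
#' @return Named vector `c(geometric, arithmetic)`.
#' @export
average_trial_likelihood <- function(params, data, prob_floor = 1e-12,
                                     reset_blocks = TRUE) {
  p <- trace_probs(params, data, reset_blocks)
  ll <- sum(log(pmax(p, prob_floor)))
  c(geometric = exp(ll / nrow(data)), arithmetic = mean(p))
}

#' One-step-ahead prediction of each observed choice
#'
#' The probability the model assigns to the choice the agent actually made
#' on each trial, conditioning on the agent's own history (its actual
#' choices and rewards up to the previous trial) — deliberately distinct
#' from free simulation, whose trajectories diverge from the data.
#' The product of this vector equals `exp(-NLL)` up to the likelihood's
#' probability floor.
#'
#' @inheritParams negative_log_likelihood
#' @return Numeric vector of length T.
#' @export
one_step_predictions <- function(params, data, reset_blocks = TRUE) {
  trace_probs(params, data, reset_blocks)
}

#' Posterior predictive check
#'
#' Simulates `n_sims` sessions at the given (typically fitted) parameters
#' and computes the same model-independent measures on the simulations as
#' on the observed data: stay probabilities, early/late performance and
#' the learning curve. Observed values can then be compared with the
#' central simulation band; an observed measure far outside the band means
#' the fitted model does not reproduce that aspect of behavior even though
#' it may score a good likelihood.
#'
#' @param params A [param_set()] (e.g. `fit$best_params`).
#' @param task Task to simulate on.
#' @param n_sims Number of simulated sessions.
#' @param seed Seed for the simulations.
#' @param observed Optional observed [behav_data()] to place alongside the
#'   simulation bands.
#' @param window Early/late window length.
#' @param reset_blocks Reset learner state per block during simulation.
#' @return A list of class `ppc_report` with elements `simulated` (per-sim
#'   measures), `bands` (2.5/50/97.5 percent quantiles per measure),
#'   `learning_curve` (mean simulated curve), `observed` (measures of the
#'   observed data, or `NULL`).
#' @export
posterior_predictive <- function(params, task, n_sims = 100L, seed = 1L,
                                 observed = NULL, window = 10L,
                                 reset_blocks = TRUE) {
  if (n_sims < 1L) stop("n_sims must be >= 1", call. = FALSE)
  sims <- lapply(seq_len(n_sims), function(i) {
    simulate_agent(params, task,
                   seed = (seed * 1000L + i) %% 2147483647L,
                   reset_blocks = reset_blocks,
                   agent_id = paste0("sim", i))
  })
  measure <- function(d) {
    sp <- suppressWarnings(stay_probability(d))
    pc <- performance_curves(d, task, window)
    c(stay_win = unname(sp["stay_win"]), stay_lose = unname(sp["stay_lose"]),
      perf_early = pc$perf_early, perf_late = pc$perf_late)
  }
  sim_measures <- t(vapply(sims, measure, numeric(4)))
  bands <- apply(sim_measures, 2, quantile,
                 probs = c(0.025, 0.5, 0.975), na.rm = TRUE)
  curves <- vapply(sims, function(d) {
    performance_curves(d, task, window)$learning_curve
  }, performance_curves(sims[[1]], task, window)$learning_curve)
  obs <- if (!is.null(observed)) {
    c(measure(observed),
      list_curve = list(performance_curves(observed, task, window)$learning_curve))
  } else NULL
  structure(list(simulated = as.data.frame(sim_measures), bands = bands,
                 learning_curve = rowMeans(as.matrix(curves)),
                 observed = if (is.null(obs)) NULL else
                   list(measures = obs[setdiff(names(obs), "list_curve")],
                        learning_curve = obs$list_curve),
                 n_sims = n_sims),
            class = "ppc_report")
}

#' @export
print.ppc_report <- function(x, ...) {
  cat("<ppc_report>", x$n_sims, "simulations\n")
  print(round(x$bands, 3))
  if (!is.null(x$observed)) {
    cat("observed:\n")
    print(round(unlist(x$observed$measures), 3))
  }
  invisible(x)
}

#' Yoked latent-variable extraction
#'
#' Replays the dataset's actual choices and rewards through the model's
#' update equations — no choice sampling occurs — and records, per trial:
#' the option values `Q` and choice kernels `CK` *before* the trial's
#' update, the full choice-probability vector, the probability of the
#' observed choice, and the reward prediction error
#' `delta = r_t - Q_t(chosen)`. These trial-by-trial trajectories are the
#' model's hidden variables aligned to the data, ready to be regressed
#' against any external signal.
#'
#' @inheritParams negative_log_likelihood
#' @return A list of class `latent_trajectories`: matrices `q` (T x K; for
#'   state-based learners the current stimulus's row), `ck` (T x K),
#'   `choice_prob` (T x K), vectors `p_chosen` and `prediction_error`.
#' @export
extract_latents <- function(params, data, reset_blocks = TRUE) {
  info <- model_info(params$model_id)
  K <- n_choices_of(data)
  T_n <- nrow(data)
  task <- attr(data, "task")
  # minimal task stand-in for init_state when none is attached
  if (is.null(task)) {
    task <- if (info$needs_stimulus) {
      ns <- max(data$stimulus, na.rm = TRUE)
      structure(list(n_trials = T_n, n_stimuli = ns, n_actions = K,
                     correct_action = rep(1L, ns),
                     stimulus_schedule = data$stimulus, block_starts = 1L),
                class = "stimulus_task")
    } else {
      structure(list(n_arms = K, n_trials = T_n,
                     reward_probs = matrix(0.5, T_n, K), block_starts = 1L),
                class = "bandit_task")
    }
  }
  q <- matrix(NA_real_, T_n, K); ck <- matrix(NA_real_, T_n, K)
  probs <- matrix(NA_real_, T_n, K)
  p_chosen <- numeric(T_n); delta <- numeric(T_n)
  state <- init_state(params, task)
  for (t in seq_len(T_n)) {
    if (reset_blocks && t > 1L && data$block[t] != data$block[t - 1L]) {
      state <- init_state(params, task)
    }
    s <- if (info$needs_stimulus) data$stimulus[t] else NULL
    q[t, ] <- if (params$model_id == "stateRL") state$q[s, ] else state$q
    ck[t, ] <- state$ck
    probs[t, ] <- choice_probs(params, state, stimulus = s)
    c_t <- data$choice[t]; r_t <- data$reward[t]
    p_chosen[t] <- probs[t, c_t]
    delta[t] <- r_t - q[t, c_t]
    state <- update_state(params, state, c_t, r_t, stimulus = s)
  }
  structure(list(q = q, ck = ck, choice_prob = probs, p_chosen = p_chosen,
                 prediction_error = delta, model_id = params$model_id),
            class = "latent_trajectories")
}

#' @export
print.latent_trajectories <- function(x, ...) {
  cat("<latent_trajectories>", x$model_id, "-", nrow(x$q), "trials\n")
  cat("mean |prediction error| =", round(mean(abs(x$prediction_error)), 3),
      "\n")
  invisible(x)
}
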