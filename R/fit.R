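`%||%` <- function(a, b) if (is.null(a)) b else a

# Shared replay: per-trial probability of each observed choice, computed by
# the compiled core. All likelihood-based quantities go through this.
trace_probs <- function(params, data, reset_blocks = TRUE) {
  info <- model_info(params$model_id)
  K <- n_choices_of(data)
  if (info$two_arms_only && K != 2L) {
    stop(params$model_id, " is defined for two options only", call. = FALSE)
  }
  stim <- data$stimulus
  n_stimuli <- 1L
  if (info$needs_stimulus) {
    if (all(is.na(stim))) {
      stop(params$model_id, " requires a stimulus column", call. = FALSE)
    }
    n_stimuli <- max(stim, na.rm = TRUE)
  }
  stim[is.na(stim)] <- 1L
  choice_prob_trace_cpp(info$code,
                        as.numeric(params$values[info$params]),
                        data$choice, data$reward, stim, data$block,
                        K, n_stimuli, params$q0, reset_blocks)
}

#' Negative log-likelihood of a dataset under a model
#'
#' Replays the dataset's own choices and rewards through the model's
#' update equations and returns minus the summed log probability of the
#' observed choices. Per-trial probabilities are clipped at `prob_floor`
#' before taking logs, so the result is finite for every parameter point
#' inside the bounds (including boundary values such as `beta = 0` or
#' `epsilon = 1`).
#'
#' @param params A [param_set()].
#' @param data A [behav_data()].
#' @param prob_floor Clip applied to choice probabilities before `log`.
#' @param reset_blocks Re-initialize learner state at block boundaries
#'   (matters only for multi-block datasets).
#' @return Scalar negative log-likelihood (always finite, non-negative).
#' @export
negative_log_likelihood <- function(params, data, prob_floor = 1e-12,
                                    reset_blocks = TRUE) {
  p <- trace_probs(params, data, reset_blocks)
  -sum(log(pmax(p, prob_floor)))
}

#' Options controlling maximum-likelihood fitting
#'
#' @param n_starts Number of random initial points for the multistart
#'   search (default 10).
#' @param seed Seed from which all start points are drawn.
#' @param prob_floor Probability clip used inside the likelihood; must lie
#'   in (0, 1e-6].
#' @param lower,upper Optional named vectors overriding the model's default
#'   box bounds.
#' @param start_sampler Optional named list of functions (one per
#'   parameter, each taking `n`) used to draw initial points; defaults to
#'   the model's default priors so that starts cover the plausible region.
#' @param maxit Iteration cap per optimizer run.
#' @param q0 Initial option value used when replaying/fitting.
#' @param reset_blocks Reset learner state at block boundaries.
#' @return A list of class `fit_options`.
#' @export
fit_options <- function(n_starts = 10L, seed = 1L, prob_floor = 1e-12,
                        lower = NULL, upper = NULL, start_sampler = NULL,
                        maxit = 500L, q0 = 0, reset_blocks = TRUE) {
  if (n_starts < 1L) stop("n_starts must be >= 1", call. = FALSE)
  if (prob_floor <= 0 || prob_floor > 1e-6) {
    stop("prob_floor must lie in (0, 1e-6]", call. = FALSE)
  }
  structure(list(n_starts = as.integer(n_starts), seed = as.integer(seed),
                 prob_floor = prob_floor, lower = lower, upper = upper,
                 start_sampler = start_sampler, maxit = as.integer(maxit),
                 q0 = q0, reset_blocks = reset_blocks),
            class = "fit_options")
}

# One bounded local optimization from a given start. Brent for univariate
# problems; L-BFGS-B otherwise, with a Nelder-Mead fallback on an
# unconstrained logistic reparameterization if L-BFGS-B errors out.
run_one_start <- function(fn, start, lower, upper, maxit) {
  k <- length(start)
  if (k == 1L) {
    res <- optim(start, fn, method = "Brent", lower = lower, upper = upper,
                 control = list(maxit = maxit))
    return(list(par = res$par, value = res$value, converged = TRUE))
  }
  res <- tryCatch(
    optim(start, fn, method = "L-BFGS-B", lower = lower, upper = upper,
          control = list(maxit = maxit)),
    error = function(e) NULL
  )
  if (!is.null(res) && is.finite(res$value)) {
    return(list(par = res$par, value = res$value,
                converged = res$convergence == 0L))
  }
  # fallback: map R^k onto the box through a logistic squash
  to_box <- function(z) lower + (upper - lower) / (1 + exp(-z))
  from_box <- function(p) {
    f <- pmin(pmax((p - lower) / (upper - lower), 1e-6), 1 - 1e-6)
    log(f / (1 - f))
  }
  res <- optim(from_box(start), function(z) fn(to_box(z)),
               method = "Nelder-Mead", control = list(maxit = 5L * maxit))
  list(par = to_box(res$par), value = res$value,
       converged = res$convergence == 0L)
}

#' Fit a model to a dataset by multistart maximum likelihood
#'
#' Minimizes the negative log-likelihood with a bounded local optimizer
#' from `n_starts` random initial points, recording every start so the
#' thoroughness of the search can be audited with
#' [multistart_diagnostics()]. Solutions sitting on a bound are flagged
#' per start (`at_bound`): a best fit on the boundary is often a red flag
#' for ill-chosen constraints or an unidentifiable parameter.
#'
#' @param model_id Model identifier.
#' @param data A [behav_data()].
#' @param options A [fit_options()].
#' @return An object of class `fit_result`: `best_params` (a
#'   [param_set()]), `best_loglik`, `n_trials`, and a per-start data frame
#'   `starts` with the initial point, final point, final negative
#'   log-likelihood, convergence and boundary flags.
#' @examples
#' d <- simulate_agent(param_set("M1", b = 0.3), bandit_task(2, 200, c(.2, .8)), seed = 1)
#' fit_mle("M1", d, fit_options(n_starts = 3))
#' @export
fit_mle <- function(model_id, data, options = fit_options()) {
  info <- model_info(model_id)
  k <- length(info$params)
  lower <- (options$lower %||% info$lower)[info$params]
  upper <- (options$upper %||% info$upper)[info$params]
  sampler <- options$start_sampler %||% default_priors(model_id)

  set.seed(options$seed)
  # half the starts from the priors (plausible region), half uniform over
  # the box, so narrow basins outside the prior mass are still reachable
  starts <- vapply(info$params, function(nm) {
    pmin(pmax(sampler[[nm]](options$n_starts), lower[nm]), upper[nm])
  }, numeric(options$n_starts))
  starts <- matrix(starts, nrow = options$n_starts, ncol = k,
                   dimnames = list(NULL, info$params))
  if (options$n_starts > 1L) {
    unif_rows <- seq(2L, options$n_starts, by = 2L)
    for (j in seq_len(k)) {
      starts[unif_rows, j] <- runif(length(unif_rows), lower[j], upper[j])
    }
  }

  fn <- function(par) {
    ps <- structure(list(model_id = model_id,
                         values = setNames(par, info$params),
                         q0 = options$q0), class = "param_set")
    negative_log_likelihood(ps, data, prob_floor = options$prob_floor,
                            reset_blocks = options$reset_blocks)
  }

  rows <- vector("list", options$n_starts)
  for (i in seq_len(options$n_starts)) {
    res <- tryCatch(
      run_one_start(fn, starts[i, ], lower, upper, options$maxit),
      error = function(e) NULL
    )
    if (is.null(res) || !is.finite(res$value)) {
      rows[[i]] <- data.frame(start = i, converged = FALSE, nll = NA_real_,
                              at_bound = NA)
      next
    }
    at_bound <- any(res$par <= lower + 1e-6 & lower > 0) ||
      any(res$par >= upper - 1e-6)
    row <- data.frame(start = i, converged = res$converged, nll = res$value,
                      at_bound = at_bound)
    for (j in seq_len(k)) {
      row[[paste0("init_", info$params[j])]] <- starts[i, j]
      row[[paste0("fit_", info$params[j])]] <- res$par[j]
    }
    rows[[i]] <- row
  }
  tab <- do.call(rbind, lapply(rows, function(r) {
    # pad failed rows with NA parameter columns
    for (nm in c(paste0("init_", info$params), paste0("fit_", info$params))) {
      if (is.null(r[[nm]])) r[[nm]] <- NA_real_
    }
    r
  }))
  ok <- which(is.finite(tab$nll))
  if (!length(ok)) stop("all optimization starts failed", call. = FALSE)
  best <- ok[which.min(tab$nll[ok])]
  best_par <- as.numeric(tab[best, paste0("fit_", info$params)])
  best_params <- do.call(param_set,
                         c(list(model_id), as.list(setNames(best_par, info$params)),
                           list(q0 = options$q0)))
  structure(list(model_id = model_id, best_params = best_params,
                 best_loglik = -tab$nll[best], n_trials = nrow(data),
                 starts = tab, options = options),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("<fit_result>", x$model_id, " LL =", round(x$best_loglik, 3),
      " (", sum(is.finite(x$starts$nll)), "of", nrow(x$starts),
      "starts ok )\n")
  print(round(x$best_params$values, 4))
  invisible(x)
}

#' Multistart convergence diagnostics
#'
#' Summarizes how the best solution evolved with the number of starting
#' points: the running-best log-likelihood (non-decreasing by
#' construction) and the Euclidean distance from the running-best
#' parameter vector to the final best one (ends at 0). A plateau in both
#' columns indicates that enough starts were used.
#'
#' @param fit A [fit_mle()] result.
#' @return Data frame with columns `n_starts`, `best_loglik_so_far`,
#'   `dist_to_final_best`.
#' @export
multistart_diagnostics <- function(fit) {
  tab <- fit$starts
  info <- model_info(fit$model_id)
  nll <- tab$nll
  nll[!is.finite(nll)] <- Inf
  fitted <- as.matrix(tab[, paste0("fit_", info$params), drop = FALSE])
  best_so_far <- integer(nrow(tab))
  b <- 1L
  for (i in seq_len(nrow(tab))) {
    if (nll[i] < nll[b]) b <- i
    best_so_far[i] <- b
  }
  final <- fitted[best_so_far[nrow(tab)], ]
  data.frame(
    n_starts = seq_len(nrow(tab)),
    best_loglik_so_far = -nll[best_so_far],
    dist_to_final_best = vapply(best_so_far, function(i) {
      sqrt(sum((fitted[i, ] - final)^2))
    }, numeric(1))
  )
}
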