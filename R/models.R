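#' @useDynLib banditfit, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats optim runif rexp quantile cor sd setNames
#' @importFrom utils read.csv write.csv
NULL

# Registry of the behavioral models. Parameter order here is the canonical
# order used throughout (optimizer vectors, CSV/JSON output, C++ core).
.model_registry <- list(
  M1 = list(
    label = "random responding with bias",
    params = "b",
    lower = c(b = 0), upper = c(b = 1),
    needs_stimulus = FALSE, two_arms_only = TRUE, code = 1L
  ),
  M2 = list(
    label = "noisy win-stay-lose-shift",
    params = "epsilon",
    lower = c(epsilon = 0), upper = c(epsilon = 1),
    needs_stimulus = FALSE, two_arms_only = TRUE, code = 2L
  ),
  M3 = list(
    label = "Rescorla-Wagner + softmax",
    params = c("alpha", "beta"),
    lower = c(alpha = 0, beta = 0), upper = c(alpha = 1, beta = 30),
    needs_stimulus = FALSE, two_arms_only = FALSE, code = 3L
  ),
  M4 = list(
    label = "choice kernel",
    params = c("alpha_c", "beta_c"),
    lower = c(alpha_c = 0, beta_c = 0), upper = c(alpha_c = 1, beta_c = 30),
    needs_stimulus = FALSE, two_arms_only = FALSE, code = 4L
  ),
  M5 = list(
    label = "Rescorla-Wagner + choice kernel",
    params = c("alpha", "beta", "alpha_c", "beta_c"),
    lower = c(alpha = 0, beta = 0, alpha_c = 0, beta_c = 0),
    upper = c(alpha = 1, beta = 30, alpha_c = 1, beta_c = 30),
    needs_stimulus = FALSE, two_arms_only = FALSE, code = 5L
  ),
  M3bias = list(
    label = "Rescorla-Wagner + softmax + side bias",
    params = c("alpha", "beta", "bias"),
    lower = c(alpha = 0, beta = 0, bias = -10),
    upper = c(alpha = 1, beta = 30, bias = 10),
    needs_stimulus = FALSE, two_arms_only = TRUE, code = 6L
  ),
  blindRL = list(
    label = "stimulus-blind action learner",
    params = c("alpha", "beta"),
    lower = c(alpha = 0, beta = 0), upper = c(alpha = 1, beta = 30),
    needs_stimulus = TRUE, two_arms_only = FALSE, code = 7L
  ),
  stateRL = list(
    label = "state-based (stimulus x action) learner",
    params = c("alpha", "beta"),
    lower = c(alpha = 0, beta = 0), upper = c(alpha = 1, beta = 30),
    needs_stimulus = TRUE, two_arms_only = FALSE, code = 8L
  )
)

#' List available behavioral models
#'
#' @return Character vector of model identifiers.
#' @export
list_models <- function() names(.model_registry)

#' Look up the definition of a behavioral model
#'
#' @param model_id One of [list_models()].
#' @return A list with elements `label`, `params` (canonical parameter
#'   names in order), `lower`/`upper` (default box bounds), and flags
#'   `needs_stimulus` and `two_arms_only`.
#' @export
model_info <- function(model_id) {
  info <- .model_registry[[model_id]]
  if (is.null(info)) {
    stop("unknown model '", model_id, "'; see list_models()", call. = FALSE)
  }
  info
}

#' Bundle named parameter values for a model
#'
#' Creates a validated parameter set: exactly the parameters the model
#' defines must be supplied, and bounded parameters must lie within their
#' bounds. Learning rates (`alpha`, `alpha_c`), the choice bias `b` and the
#' lapse rate `epsilon` live in \[0, 1\]; inverse temperatures (`beta`,
#' `beta_c`) are non-negative; the side bias `bias` is unbounded.
#'
#' @param model_id Model identifier, see [list_models()].
#' @param ... Named scalar parameter values (e.g. `alpha = 0.1, beta = 5`).
#' @param q0 Initial option value assigned to every Q entry at the start of
#'   a session (and after each block reset). Not a fitted parameter.
#' @return An object of class `param_set`.
#' @examples
#' param_set("M3", alpha = 0.1, beta = 5)
#' @export
param_set <- function(model_id, ..., q0 = 0) {
  info <- model_info(model_id)
  values <- c(...)
  if (length(values) && (is.null(names(values)) || any(names(values) == ""))) {
    stop("all parameters must be named", call. = FALSE)
  }
  missing <- setdiff(info$params, names(values))
  if (length(missing)) {
    stop(model_id, " requires parameter(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  extra <- setdiff(names(values), info$params)
  if (length(extra)) {
    stop("parameter(s) not in ", model_id, ": ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  values <- values[info$params]
  bad <- values < info$lower - 1e-12 | values > info$upper + 1e-12
  # side bias is conceptually unbounded; its registry bounds only box the optimizer
  bad[names(values) == "bias"] <- FALSE
  if (any(bad)) {
    stop("parameter(s) out of bounds: ",
         paste(names(values)[bad], collapse = ", "), call. = FALSE)
  }
  structure(list(model_id = model_id, values = values, q0 = q0),
            class = "param_set")
}

#' @export
print.param_set <- function(x, ...) {
  cat("<param_set>", x$model_id, "-", model_info(x$model_id)$label, "\n")
  print(round(x$values, 4))
  if (x$q0 != 0) cat("q0 =", x$q0, "\n")
  invisible(x)
}

#' @export
format.param_set <- function(x, ...) {
  paste0(x$model_id, "(", paste(names(x$values), signif(x$values, 3),
                                sep = "=", collapse = ", "), ")")
}

# Number of free parameters of a model.
n_params <- function(model_id) length(model_info(model_id)$params)

#' Initialize the internal state of a model
#'
#' Fresh state: every option value Q equals `q0` from the parameter set
#' (default 0), every choice-kernel entry is 0, and there is no previous
#' choice or reward. State-based learners hold one Q value per
#' (stimulus, action) pair; all other models hold one per option.
#'
#' @param params A [param_set()].
#' @param task A task configuration ([bandit_task()], [reversal_task()] or
#'   [stimulus_task()]).
#' @return An object of class `model_state` with fields `q`, `ck`,
#'   `last_choice`, `last_reward`.
#' @export
init_state <- function(params, task) {
  info <- model_info(params$model_id)
  is_stim <- inherits(task, "stimulus_task")
  if (info$needs_stimulus && !is_stim) {
    stop(params$model_id, " requires a stimulus task", call. = FALSE)
  }
  n_arms <- if (is_stim) task$n_actions else task$n_arms
  if (info$two_arms_only && n_arms != 2L) {
    stop(params$model_id, " is defined for two options only", call. = FALSE)
  }
  q <- if (params$model_id == "stateRL") {
    matrix(params$q0, nrow = task$n_stimuli, ncol = task$n_actions)
  } else {
    rep(params$q0, n_arms)
  }
  structure(list(q = q, ck = rep(0, n_arms),
                 last_choice = NA_integer_, last_reward = NA_integer_),
            class = "model_state")
}

softmax <- function(drive) {
  e <- exp(drive - max(drive))
  e / sum(e)
}

#' Per-trial choice probabilities of a model
#'
#' Evaluates the probability of each option given the current internal
#' state. The random responder returns `(b, 1 - b)`; noisy
#' win-stay-lose-shift puts probability `1 - epsilon/2` on the option
#' consistent with repeating a win or leaving a loss (uniform on the first
#' trial, when there is no previous outcome); value and kernel learners use
#' a softmax over `beta * Q + beta_c * CK` (whichever components the model
#' carries); the side-bias variant adds `bias` to the first (left) option's
#' value inside the softmax.
#'
#' @param params A [param_set()].
#' @param state A `model_state` from [init_state()] / [update_state()].
#' @param stimulus Current stimulus index (state-based learners only).
#' @return Numeric probability vector over options; non-negative, sums to 1.
#' @export
choice_probs <- function(params, state, stimulus = NULL) {
  v <- params$values
  switch(params$model_id,
    M1 = c(v[["b"]], 1 - v[["b"]]),
    M2 = {
      if (is.na(state$last_choice)) {
        rep(0.5, 2)
      } else {
        eps <- v[["epsilon"]]
        # option consistent with win-stay-lose-shift
        stay <- state$last_reward == 1L
        target <- if (stay) state$last_choice else 3L - state$last_choice
        p <- rep(eps / 2, 2)
        p[target] <- 1 - eps / 2
        p
      }
    },
    M3 = softmax(v[["beta"]] * state$q),
    M4 = softmax(v[["beta_c"]] * state$ck),
    M5 = softmax(v[["beta"]] * state$q + v[["beta_c"]] * state$ck),
    M3bias = softmax(v[["beta"]] * (state$q + c(v[["bias"]], 0))),
    blindRL = softmax(v[["beta"]] * state$q),
    stateRL = {
      if (is.null(stimulus)) stop("stateRL requires a stimulus", call. = FALSE)
      softmax(v[["beta"]] * state$q[stimulus, ])
    },
    stop("unknown model '", params$model_id, "'", call. = FALSE)
  )
}

#' Advance a model's internal state after a choice and outcome
#'
#' Value learners apply the delta rule to the chosen option only:
#' `Q[k] <- Q[k] + alpha * (r - Q[k])`. Kernel learners update every
#' option's kernel toward the indicator of having just been chosen:
#' `CK[k] <- CK[k] + alpha_c * (a_k - CK[k])` with `a_k = 1` for the chosen
#' option and 0 otherwise. The previous choice and reward are recorded for
#' the win-stay-lose-shift rule. Components a model does not use are left
#' untouched.
#'
#' @inheritParams choice_probs
#' @param choice Chosen option index (1-based).
#' @param reward Binary reward (0/1).
#' @return The updated `model_state`.
#' @export
update_state <- function(params, state, choice, reward, stimulus = NULL) {
  v <- params$values
  id <- params$model_id
  if (id %in% c("M3", "M5", "M3bias", "blindRL")) {
    state$q[choice] <- state$q[choice] + v[["alpha"]] * (reward - state$q[choice])
  } else if (id == "stateRL") {
    if (is.null(stimulus)) stop("stateRL requires a stimulus", call. = FALSE)
    q <- state$q[stimulus, choice]
    state$q[stimulus, choice] <- q + v[["alpha"]] * (reward - q)
  }
  if (id %in% c("M4", "M5")) {
    a <- as.numeric(seq_along(state$ck) == choice)
    state$ck <- state$ck + v[["alpha_c"]] * (a - state$ck)
  }
  state$last_choice <- as.integer(choice)
  state$last_reward <- as.integer(reward)
  state
}
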