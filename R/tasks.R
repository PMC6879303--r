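#' Stationary multi-armed Bernoulli bandit task
#'
#' Defines a K-armed bandit in which arm k pays a binary reward with a
#' fixed probability on every trial. The canonical workbench example is a
#' two-armed bandit over 1000 trials with reward probabilities 0.2 and 0.8.
#'
#' @param n_arms Number of arms K (>= 2).
#' @param n_trials Number of trials T (>= 1).
#' @param means Per-arm reward probabilities, length `n_arms`, each in
#'   \[0, 1\].
#' @return A `bandit_task` object holding the per-trial, per-arm reward
#'   probability matrix `reward_probs` (T x K) and, when the task is built
#'   from blocks, the 1-based `block_starts`.
#' @examples
#' bandit_task(2, 1000, c(0.2, 0.8))
#' @export
bandit_task <- function(n_arms, n_trials, means) {
  n_arms <- as.integer(n_arms); n_trials <- as.integer(n_trials)
  if (n_arms < 2L) stop("need at least two arms", call. = FALSE)
  if (n_trials < 1L) stop("need at least one trial", call. = FALSE)
  if (length(means) != n_arms) {
    stop("means must have one entry per arm", call. = FALSE)
  }
  if (any(means < 0 | means > 1)) {
    stop("reward probabilities must lie in [0, 1]", call. = FALSE)
  }
  probs <- matrix(rep(as.numeric(means), each = n_trials),
                  nrow = n_trials, ncol = n_arms)
  structure(list(n_arms = n_arms, n_trials = n_trials,
                 reward_probs = probs, block_starts = 1L),
            class = "bandit_task")
}

#' Block-structured reversal bandit task
#'
#' Concatenates `n_blocks` independent bandit blocks of `block_len` trials
#' each; the per-arm reward probabilities cycle through `mean_pairs`
#' (recycled), e.g. alternating `c(0.2, 0.8)` and `c(0.8, 0.2)` so the good
#' arm reverses between blocks. `block_starts` records where each block
#' begins so that model runners can reset learner state per block; the task
#' itself carries no reset semantics.
#'
#' @param n_blocks Number of blocks.
#' @param block_len Trials per block.
#' @param mean_pairs List of per-arm probability vectors, one per block
#'   pattern (recycled across blocks).
#' @return A `bandit_task` with T = `n_blocks * block_len` rows and
#'   populated `block_starts`.
#' @examples
#' reversal_task(10, 50, list(c(0.2, 0.8), c(0.8, 0.2)))
#' @export
reversal_task <- function(n_blocks, block_len, mean_pairs) {
  n_blocks <- as.integer(n_blocks); block_len <- as.integer(block_len)
  if (n_blocks < 1L || block_len < 1L) {
    stop("n_blocks and block_len must be positive", call. = FALSE)
  }
  if (!length(mean_pairs)) stop("mean_pairs must be non-empty", call. = FALSE)
  mean_pairs <- lapply(mean_pairs, as.numeric)
  n_arms <- length(mean_pairs[[1]])
  if (n_arms < 2L) stop("need at least two arms", call. = FALSE)
  if (any(vapply(mean_pairs, length, 1L) != n_arms)) {
    stop("all mean_pairs entries must have the same length", call. = FALSE)
  }
  if (any(unlist(mean_pairs) < 0 | unlist(mean_pairs) > 1)) {
    stop("reward probabilities must lie in [0, 1]", call. = FALSE)
  }
  rows <- do.call(rbind, lapply(seq_len(n_blocks), function(b) {
    mu <- mean_pairs[[(b - 1L) %% length(mean_pairs) + 1L]]
    matrix(rep(mu, each = block_len), nrow = block_len)
  }))
  structure(list(n_arms = n_arms, n_trials = n_blocks * block_len,
                 reward_probs = rows,
                 block_starts = seq(1L, n_blocks * block_len, by = block_len)),
            class = "bandit_task")
}

#' Deterministic stimulus-action learning task
#'
#' On each trial one of `n_stimuli` stimuli is shown and exactly one action
#' is rewarded: the action mapped to that stimulus by `correct_action`.
#' The default instantiation has three stimuli and three actions with the
#' mapping s1 -> a1, s2 -> a1, s3 -> a3, so action a2 is never correct and
#' a stimulus-blind policy can score at most 2/3.
#'
#' @param n_trials Number of trials.
#' @param n_stimuli Number of distinct stimuli.
#' @param n_actions Number of available actions.
#' @param correct_action Integer vector mapping stimulus to its rewarded
#'   action.
#' @param stimulus_schedule Optional per-trial stimulus sequence (1-based,
#'   length `n_trials`). When `NULL`, a uniform random schedule is drawn
#'   with `schedule_seed`.
#' @param schedule_seed Seed used only when the schedule is drawn.
#' @return A `stimulus_task` object.
#' @export
stimulus_task <- function(n_trials, n_stimuli = 3L, n_actions = 3L,
                          correct_action = c(1L, 1L, 3L),
                          stimulus_schedule = NULL, schedule_seed = 1L) {
  n_trials <- as.integer(n_trials)
  n_stimuli <- as.integer(n_stimuli); n_actions <- as.integer(n_actions)
  if (length(correct_action) != n_stimuli) {
    stop("correct_action must map every stimulus", call. = FALSE)
  }
  if (any(correct_action < 1L | correct_action > n_actions)) {
    stop("correct_action entries must be valid actions", call. = FALSE)
  }
  if (is.null(stimulus_schedule)) {
    stimulus_schedule <- local({
      old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
      set.seed(schedule_seed)
      sample.int(n_stimuli, n_trials, replace = TRUE)
    })
  }
  stimulus_schedule <- as.integer(stimulus_schedule)
  if (length(stimulus_schedule) != n_trials ||
      any(stimulus_schedule < 1L | stimulus_schedule > n_stimuli)) {
    stop("stimulus_schedule must be n_trials valid stimulus indices",
         call. = FALSE)
  }
  structure(list(n_trials = n_trials, n_stimuli = n_stimuli,
                 n_actions = n_actions,
                 correct_action = as.integer(correct_action),
                 stimulus_schedule = stimulus_schedule,
                 block_starts = 1L),
            class = "stimulus_task")
}

#' Realize the reward for a choice on one trial
#'
#' For bandit tasks the reward is a Bernoulli draw with the chosen arm's
#' probability on that trial (using the current RNG stream); for stimulus
#' tasks it is deterministic: 1 iff the chosen action is the correct action
#' for the trial's stimulus. Only the chosen option's outcome is realized.
#'
#' @param task A task object.
#' @param trial Trial index (1-based).
#' @param choice Chosen arm/action (1-based).
#' @return 0 or 1.
#' @export
draw_reward <- function(task, trial, choice) {
  trial <- as.integer(trial); choice <- as.integer(choice)
  if (trial < 1L || trial > task$n_trials) stop("invalid trial", call. = FALSE)
  if (inherits(task, "stimulus_task")) {
    if (choice < 1L || choice > task$n_actions) {
      stop("invalid action", call. = FALSE)
    }
    s <- task$stimulus_schedule[trial]
    as.integer(choice == task$correct_action[s])
  } else {
    if (choice < 1L || choice > task$n_arms) stop("invalid arm", call. = FALSE)
    as.integer(runif(1) < task$reward_probs[trial, choice])
  }
}

# Per-trial block id implied by block_starts (1-based run-length encoding).
block_ids <- function(task) {
  starts <- task$block_starts
  rep(seq_along(starts),
      times = diff(c(starts, task$n_trials + 1L)))
}

# The uniquely best option per trial; errors when no unique argmax exists.
correct_option <- function(task) {
  if (inherits(task, "stimulus_task")) {
    return(task$correct_action[task$stimulus_schedule])
  }
  probs <- task$reward_probs
  best <- max.col(probs, ties.method = "first")
  tied <- vapply(seq_len(nrow(probs)), function(t) {
    sum(probs[t, ] == probs[t, best[t]]) > 1L
  }, logical(1))
  if (any(tied)) {
    stop("no unique correct option on trial ", which(tied)[1], call. = FALSE)
  }
  best
}

#' Serialize a task configuration to JSON
#'
#' @param task A task object.
#' @param path Optional file path; when `NULL` the JSON string is returned.
#' @return JSON string (invisibly when written to a file).
#' @export
task_to_json <- function(task, path = NULL) {
  x <- unclass(task)
  x$type <- class(task)[1]
  x$reward_probs <- NULL
  if (inherits(task, "bandit_task")) {
    # store compactly: unique per-block rows + block starts
    starts <- task$block_starts
    x$block_means <- lapply(starts, function(s) task$reward_probs[s, ])
  }
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Deserialize a task configuration from JSON
#'
#' @param json JSON string or file path produced by [task_to_json()].
#' @return The reconstructed task object.
#' @export
task_from_json <- function(json) {
  x <- jsonlite::fromJSON(json)
  if (identical(x$type, "stimulus_task")) {
    return(stimulus_task(x$n_trials, x$n_stimuli, x$n_actions,
                         x$correct_action, x$stimulus_schedule))
  }
  starts <- as.integer(x$block_starts)
  means <- x$block_means
  if (is.matrix(means)) means <- lapply(seq_len(nrow(means)), function(i) means[i, ])
  if (length(starts) == 1L) {
    return(bandit_task(x$n_arms, x$n_trials, means[[1]]))
  }
  lens <- diff(c(starts, x$n_trials + 1L))
  if (length(unique(lens)) == 1L) {
    return(reversal_task(length(starts), lens[1], means))
  }
  rows <- do.call(rbind, Map(function(mu, len) {
    matrix(rep(as.numeric(mu), each = len), nrow = len)
  }, means, lens))
  structure(list(n_arms = x$n_arms, n_trials = x$n_trials,
                 reward_probs = rows, block_starts = starts),
            class = "bandit_task")
}
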