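#' Construct a trial-level behavioral dataset
#'
#' The container for one agent's (or subject's) session: ordered trials
#' with a choice and a binary reward, plus optional block and stimulus
#' columns. Choices and stimuli are 1-based everywhere, in memory and on
#' disk.
#'
#' @param choice Integer vector of choices in `1..n_choices`.
#' @param reward Binary reward vector (0/1), same length.
#' @param n_choices Number of available options K.
#' @param block Optional per-trial block id (defaults to a single block).
#' @param stimulus Optional per-trial stimulus index.
#' @param agent_id Label for the agent/subject.
#' @param task Optional generating task object, kept as an attribute.
#' @return A data frame of class `behav_data` with columns `trial`,
#'   `block`, `stimulus`, `choice`, `reward` and attributes `agent_id`,
#'   `n_choices`, `task`.
#' @export
behav_data <- function(choice, reward, n_choices, block = NULL,
                       stimulus = NULL, agent_id = "agent1", task = NULL) {
  choice <- as.integer(choice); reward <- as.integer(reward)
  n <- length(choice)
  if (length(reward) != n) stop("choice and reward lengths differ", call. = FALSE)
  if (n < 1L) stop("dataset must contain at least one trial", call. = FALSE)
  if (any(!reward %in% c(0L, 1L))) {
    stop("rewards must be binary (0/1)", call. = FALSE)
  }
  n_choices <- as.integer(n_choices)
  if (any(choice < 1L | choice > n_choices)) {
    stop("choices must lie in 1..", n_choices, call. = FALSE)
  }
  if (is.null(block)) block <- rep(1L, n)
  block <- as.integer(block)
  if (length(block) != n) stop("block length mismatch", call. = FALSE)
  if (any(diff(block) < 0L)) {
    stop("block ids must be non-decreasing", call. = FALSE)
  }
  if (!is.null(stimulus)) {
    stimulus <- as.integer(stimulus)
    if (length(stimulus) != n) stop("stimulus length mismatch", call. = FALSE)
    if (any(stimulus < 1L)) stop("stimulus indices are 1-based", call. = FALSE)
  } else {
    stimulus <- rep(NA_integer_, n)
  }
  df <- data.frame(trial = seq_len(n), block = block, stimulus = stimulus,
                   choice = choice, reward = reward)
  structure(df, class = c("behav_data", "data.frame"),
            agent_id = agent_id, n_choices = n_choices, task = task)
}

#' @export
print.behav_data <- function(x, ...) {
  cat("<behav_data> agent", attr(x, "agent_id"), "-", nrow(x), "trials,",
      attr(x, "n_choices"), "options\n")
  print.data.frame(utils::head(as.data.frame(x), 6), row.names = FALSE)
  if (nrow(x) > 6) cat("...", nrow(x) - 6, "more trials\n")
  invisible(x)
}

n_choices_of <- function(data) attr(data, "n_choices")

#' Simulate an agent performing a task
#'
#' Generates a full session by alternating, on each trial: evaluate the
#' model's choice probabilities, sample a choice, realize the reward from
#' the task, and update the model's state. When the task has multiple
#' blocks and `reset_blocks` is `TRUE`, the learner's state is re-initialized
#' at every block start (each block treated as an independent session).
#' The per-trial probability assigned to the sampled choice is recorded in
#' attribute `sim_choice_prob` so that likelihood replay can be checked
#' against the generative pass exactly.
#'
#' @param params A [param_set()].
#' @param task A task object.
#' @param seed Integer seed; fixed seed gives a bit-reproducible session.
#' @param reset_blocks Reset learner state at block boundaries (default
#'   `TRUE`; only relevant for multi-block tasks).
#' @param agent_id Label stored on the dataset.
#' @return A [behav_data()] with the generating `params` attached as
#'   attribute `params`.
#' @examples
#' task <- bandit_task(2, 100, c(0.2, 0.8))
#' d <- simulate_agent(param_set("M3", alpha = 0.1, beta = 5), task, seed = 1)
#' @export
simulate_agent <- function(params, task, seed = NULL, reset_blocks = TRUE,
                           agent_id = "agent1") {
  if (!is.null(seed)) set.seed(as.integer(seed))
  is_stim <- inherits(task, "stimulus_task")
  n_opts <- if (is_stim) task$n_actions else task$n_arms
  T_n <- task$n_trials
  blocks <- block_ids(task)
  state <- init_state(params, task)
  choice <- integer(T_n); reward <- integer(T_n); pchosen <- numeric(T_n)
  for (t in seq_len(T_n)) {
    if (reset_blocks && t > 1L && blocks[t] != blocks[t - 1L]) {
      state <- init_state(params, task)
    }
    s <- if (is_stim) task$stimulus_schedule[t] else NULL
    p <- choice_probs(params, state, stimulus = s)
    c_t <- sample.int(n_opts, 1L, prob = p)
    r_t <- draw_reward(task, t, c_t)
    choice[t] <- c_t; reward[t] <- r_t; pchosen[t] <- p[c_t]
    state <- update_state(params, state, c_t, r_t, stimulus = s)
  }
  out <- behav_data(choice, reward, n_choices = n_opts, block = blocks,
                    stimulus = if (is_stim) task$stimulus_schedule else NULL,
                    agent_id = agent_id, task = task)
  attr(out, "params") <- params
  attr(out, "sim_choice_prob") <- pchosen
  out
}

#' Write behavioral datasets to CSV
#'
#' One row per trial with columns `agent_id, trial, block, stimulus,
#' choice, reward`; several agents are concatenated. Stimulus cells are
#' empty for tasks without stimuli. Codes are 1-based.
#'
#' @param datasets A `behav_data` or list of them.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_behav_csv <- function(datasets, path) {
  if (inherits(datasets, "behav_data")) datasets <- list(datasets)
  rows <- do.call(rbind, lapply(datasets, function(d) {
    data.frame(agent_id = attr(d, "agent_id"), trial = d$trial,
               block = d$block, stimulus = d$stimulus,
               choice = d$choice, reward = d$reward)
  }))
  write.csv(rows, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read behavioral datasets from CSV
#'
#' Expects columns `agent_id`, `trial`, `choice`, `reward` (and optional
#' `block`, `stimulus`). Validates that rewards are binary, choices
#' positive, and trial indices contiguous from 1 within each agent;
#' violations raise errors naming the offending row.
#'
#' @param path CSV file path.
#' @param n_choices Number of options; defaults to the maximum choice code
#'   observed in the file.
#' @return Named list of [behav_data()] objects, one per agent.
#' @export
read_behav_csv <- function(path, n_choices = NULL) {
  raw <- read.csv(path, stringsAsFactors = FALSE)
  required <- c("agent_id", "trial", "choice", "reward")
  missing <- setdiff(required, names(raw))
  if (length(missing)) {
    stop("missing column(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  bad_r <- which(!raw$reward %in% c(0, 1))
  if (length(bad_r)) {
    stop("non-binary reward at data row ", bad_r[1], call. = FALSE)
  }
  bad_c <- which(is.na(raw$choice) | raw$choice < 1)
  if (length(bad_c)) {
    stop("invalid choice at data row ", bad_c[1], call. = FALSE)
  }
  if (is.null(n_choices)) n_choices <- max(raw$choice)
  out <- lapply(split(raw, raw$agent_id), function(a) {
    a <- a[order(a$trial), , drop = FALSE]
    if (!identical(as.integer(a$trial), seq_len(nrow(a)))) {
      stop("non-contiguous trial indices for agent ", a$agent_id[1],
           call. = FALSE)
    }
    stim <- if ("stimulus" %in% names(a) && any(!is.na(a$stimulus))) {
      a$stimulus
    } else NULL
    blk <- if ("block" %in% names(a)) a$block else NULL
    behav_data(a$choice, a$reward, n_choices = n_choices, block = blk,
               stimulus = stim, agent_id = as.character(a$agent_id[1]))
  })
  out[unique(as.character(raw$agent_id))]
}
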