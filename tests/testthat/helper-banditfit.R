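# Shared fixtures and oracles, built in code.

# A tiny deterministic dataset: choices/rewards fixed by hand.
tiny_data <- function(choice = c(1L, 2L, 1L, 1L, 2L),
                      reward = c(1L, 0L, 1L, 0L, 1L), n_choices = 2L) {
  behav_data(choice, reward, n_choices = n_choices)
}

# Enumerate every choice sequence of length T over K options, attach
# rewards as a fixed deterministic function of choice, and sum the
# probability each model assigns to each full sequence. For a proper
# generative model this sum must be 1.
sequence_probability_sum <- function(params, T_n = 6L, K = 2L,
                                     reward_fn = function(ch) as.integer(ch == 1L),
                                     stimulus = NULL) {
  grid <- expand.grid(rep(list(seq_len(K)), T_n))
  total <- 0
  for (i in seq_len(nrow(grid))) {
    ch <- as.integer(grid[i, ])
    d <- behav_data(ch, reward_fn(ch), n_choices = K, stimulus = stimulus)
    total <- total + prod(one_step_predictions(params, d))
  }
  total
}

# Monte-Carlo tolerance: 3 binomial standard errors.
binom_tol <- function(p, n) 3 * sqrt(p * (1 - p) / n)
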