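# banditfit

Computational modeling of trial-level choice behavior: generative models of
learning and decision making in multi-armed bandit and stimulus–action
tasks, maximum-likelihood fitting with multistart audits, BIC model
comparison with confusion/inversion matrices, parameter- and model-recovery
experiments, posterior predictive validation, and yoked latent-variable
extraction. It is aimed at behavioral and cognitive-neuroscience
researchers who fit learning models to choice data and need the full
sanity-check pipeline around the fit, not just the fit itself.

## The models

For a K-armed Bernoulli bandit (option k pays 1 with probability μₖ) the
package implements:

| id | model | parameters |
|----|-------|------------|
| M1 | biased random responding | b |
| M2 | noisy win-stay-lose-shift | ε |
| M3 | Rescorla–Wagner + softmax | α, β |
| M4 | choice kernel (perseveration) | α_c, β_c |
| M5 | Rescorla–Wagner + choice kernel | α, β, α_c, β_c |
| M3bias | M3 with a lateral side bias | α, β, B |
| blindRL / stateRL | stimulus-blind vs state-based learners | α, β |

The learning core is the delta rule, Q ← Q + α(r − Q) for the chosen
option, with softmax choice p(k) ∝ exp(βQ(k) + β_c·CK(k)); the choice
kernel CK tracks recency-weighted choice frequency, CK ← CK + α_c(a − CK)
for every option. Fitting maximizes the likelihood
L(θ) = Σₜ log p(cₜ | d₁:ₜ₋₁, θ) by replaying the subject's own history;
models are compared with BIC = −2·LL + k·ln T.

## Worked example

Simulate a Rescorla–Wagner learner (α = 0.1, β = 5) on the canonical
two-armed bandit (1000 trials, μ = 0.2/0.8), fit it back, and compare all
five models:

```r
library(banditfit)
task  <- bandit_task(2, 1000, c(0.2, 0.8))
truth <- param_set("M3", alpha = 0.1, beta = 5)
d     <- simulate_agent(truth, task, seed = 1)

fit_mle("M3", d, fit_options(n_starts = 10))
#> <fit_result> M3  LL = -178.223  ( 10 of 10 starts ok )
#>  alpha   beta
#> 0.1631 4.9558

compare_models(d, c("M1","M2","M3","M4","M5"), fit_options(n_starts = 10))
#> <comparison_result> selected: M3
#>  model k  loglik     bic
#>     M1 1 -195.56  398.03
#>     M2 1 -519.66 1046.23
#>     M3 2 -178.22  370.26
#>     M4 2 -191.78  397.37
#>     M5 4 -178.22  384.08
```

The fitted learning rate (0.16) and inverse temperature (4.96) sit near
the generating values; BIC selects the true model — M5 matches M3's
likelihood exactly (M3 is nested in it) but pays the penalty for two
unused parameters. The absolute fit is
`average_trial_likelihood(...)` = 0.837 per trial (0.5 would be chance),
and the model-independent signature
`stay_probability(d)` = (0.954 after a win, 0.758 after a loss) shows the
reward sensitivity a random responder would lack. Latent trajectories for
regression against neural data come from `extract_latents(fit$best_params, d)`
(per-trial Q values, choice probabilities, prediction errors).

Whether such a fit *means* anything is what the audit tools quantify:
`recover_parameters()` (simulate–refit correlations, e.g. learning-rate
recovery degrades when β leaves the 1–10 range), `model_recovery()` /
`invert_confusion()` (can BIC tell these models apart at your noise
level?), `compare_nested_recovery()` (cost of omitting a nuisance side
bias), and `posterior_predictive()` (does the fitted model reproduce the
learning curve it claims to explain?). `run_experiment(experiment_config("model-recovery-noisy"))`
and friends run the canned versions of these audits end to end.

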