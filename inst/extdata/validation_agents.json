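{
  "comment": "Frozen generative agents for the stimulus-action validation example: a stimulus-blind learner with low choice noise and a state-based learner with high choice noise, tuned once so the two session-average learning curves approximately coincide.",
  "blind": { "alpha": 0.25, "beta": 7.0 },
  "state": { "alpha": 0.4, "beta": 1.4 },
  "n_trials": 180,
  "n_agents": 20
}
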