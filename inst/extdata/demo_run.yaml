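# Demonstration run: synthetic cohort, logistic model, order 1-2 contrasts,
# case ablation of the alive & prior-suicide-attempt & SGA stratum.
seed: 42
model: logistic
orders: [1, 2]
contrast_features: [SGA, FGA, diuretics, cardiovascular_disease, delirium,
                    dementia_alzheimers, self_harm, antidepressants]
top_k: 5
direction: both
threshold: 0.05
figure_format: png
n_patients: 2000
ablation:
  - pattern:
      prior_suicide_attempt: 1
      SGA: 1
    outcome: 0
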