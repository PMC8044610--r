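{
  "design": {
    "distances_m": [1.00, 1.36, 1.72, 2.08, 2.44, 2.81, 3.17, 3.53, 3.89, 4.25],
    "days": 4,
    "sessions_per_day": 10,
    "reps_per_distance_per_session": 5,
    "detection_stim_probs": [0.25, 0.25, 0.5],
    "localization_stim_probs": [0.5, 0.5],
    "practice_days": [1]
  },
  "observer": {
    "form": "exponential",
    "alpha0": 3.0,
    "alpha1": -0.4,
    "beta0": 2.0,
    "beta1": -0.6,
    "c0": 0.1,
    "c1": -0.2
  },
  "participants": ["P1", "P2"],
  "sampler": {
    "chains": 4,
    "iter": 1500,
    "warmup": 1000
  }
}
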