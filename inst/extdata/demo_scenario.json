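{
  "n_individuals": 100,
  "n_sites": 6,
  "period_lengths_days": [
    10,
    20,
    6
  ],
  "event_rate_per_site_day": 25,
  "mean_flock_size": 3.8,
  "event_duration_s": 191,
  "reads_per_visit_mean": 3,
  "preference_strength": 5,
  "preference_update_rate": 0.8,
  "denied_visit_rate": 0.1,
  "n_patches": 4,
  "patch_duration_days": 4,
  "n_nestboxes": 44,
  "nestbox_mean_visitors": 1.7,
  "rng_seed": 1
}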