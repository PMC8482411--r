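schema: 1
game:
  game: bubble
  n_prompts: 50
gaze:
  theta_fix_ms: 200
  theta_phase_ms: 30000
  theta_term_ms: 120000
  gap_tol_ms: 75
profile:
  p_share: 0.95
  follow_a: 3.5
  follow_b: 0.04
  share_latency_median_ms: 900
  response_latency_median_ms: 700
  jitter_sd: 12
  sampling_hz: 55
seed: 2024
out_dir: "."
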