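# fully synthetic demo cohort: three patients, desk-scale sizes
seed: 1
n_patients: 3
window: 500
min_itx_span: 7000
sim:
  n_primary_events: 40
  shared_fraction: 0.89
  n_met_private: 6
  n_germline: 5
  jitter_sd: 100
enrichment:
  n_sims: 200
hotspots:
  bandwidth: 10000
  grid_step: 10000
  threshold: 3.0e-6
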