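# Small demonstration pipeline configuration: a coarse tumor phantom and a
# 30/15-subject cohort, sized so the full run completes in seconds.
seed: 7
fit_method: wls
gradient: {n_directions: 24, b: 1000, n_b0: 1}
phantom:
  shape: [32, 32, 8]
  snr: 30
  alpha: {left: 0.8, right: 1.0}
  tumor_radius: 8
  ptbe_thickness: 4
  tumor_side: left
cohort:
  n_glioma: 30
  n_lgg: 10
  n_control: 15
  n_female: [12, 7]
  n_idh_mut: 10
  n_types: {astrocytoma: 12, oligodendroglioma: 4, glioblastoma: 14}
  n_sides: {left: 16, right: 11, both: 3}
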