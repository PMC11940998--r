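# Demo configuration for `sersclass run` / `sersclass synth`.
# Two-class synthetic serum cohort; all seeds may be overridden by the
# CLI --seed flag.
synth:
  classes:
    label: [respiratory, referent]
    n_patients: [12, 20]
    spectra_per_patient: [3, 3]
preprocess:
  sg_window: 15
  sg_polyorder: 1
  sg_deriv: 0
  baseline_degree: 15
protocol:
  P: 5
  T_rep: 5
  train_fraction: 0.8
  K: 10
  max_lv: 15
  spectra_per_patient_draw: 3
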