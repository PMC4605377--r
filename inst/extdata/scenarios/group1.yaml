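name: group1
geometry: mouse
baseline_repeats: 5
phases:
- label: isotonic
  osmolality: 250
  duration: 10
  frames_per_min: 0.2
  tau: 2.0
  amplitudes: {cct: 0.0, acd: 0.0, lt: 0.0, crd: 0.0, lsi: 0.0, iris_sag: 0.0}
- label: hypertonic
  osmolality: 1000
  duration: 13
  frames_per_min: 1.0
  tau: 2.5
  amplitudes: {cct: -0.207, acd: -0.115, lt: 0.0, crd: -0.023, lsi: 0.288, iris_sag: 0.6853146853146853}
- label: reversal
  osmolality: 250
  duration: 40
  frames_per_min: 0.2
  tau: 6.0
  amplitudes: {cct: 0.0, acd: 0.0, lt: 0.0, crd: 0.0, lsi: 0.0, iris_sag: 0.0}
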