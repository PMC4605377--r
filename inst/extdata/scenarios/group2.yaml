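name: group2
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
  osmolality: 500
  duration: 13
  frames_per_min: 1.0
  tau: 2.8
  amplitudes: {cct: -0.1035, acd: -0.0575, lt: 0.0, crd: -0.0115, lsi: 0.144, iris_sag: 0.3426573426573427}
- label: reversal
  osmolality: 250
  duration: 40
  frames_per_min: 0.2
  tau: 7.0
  amplitudes: {cct: 0.0, acd: 0.0, lt: 0.0, crd: 0.0, lsi: 0.0, iris_sag: 0.0}
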