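name: group3
geometry: mouse
baseline_repeats: 5
phases:
- label: isotonic
  osmolality: 250
  duration: 10
  frames_per_min: 0.2
  tau: 2.0
  amplitudes: {cct: 0.0, acd: 0.0, lt: 0.0, crd: 0.0, lsi: 0.0, iris_sag: 0.0}
- label: hypotonic
  osmolality: 100
  duration: 24
  frames_per_min: 0.3333333333333333
  tau: 4.5
  amplitudes: {cct: 0.15, acd: 0.08, lt: 0.0, crd: 0.02, lsi: 0.0, iris_sag: -1.8601398601398602}
- label: reversal
  osmolality: 250
  duration: 24
  frames_per_min: 0.3333333333333333
  tau: 4.5
  amplitudes: {cct: 0.0, acd: 0.0, lt: 0.0, crd: 0.0, lsi: 0.0, iris_sag: 0.0}
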