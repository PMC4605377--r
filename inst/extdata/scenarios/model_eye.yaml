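name: model_eye
geometry: model_eye
baseline_repeats: 5
phases:
- label: isotonic
  osmolality: 250
  duration: 1
  frames_per_min: 1.0
  tau: 1.0
  amplitudes: {cct: 0.0, acd: 0.0, lt: 0.0, crd: 0.0, lsi: 0.0, iris_sag: 0.0}
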