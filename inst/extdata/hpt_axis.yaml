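# Hypothalamic-pituitary-thyroid axis preset: TRH -> TSH -> T3 chain with
# negative T3 -> TRH feedback (k = 0.5). Stimulatory edges saturate
# (sigmoid); the feedback edge acts linearly.
glands: [TRH, TSH, T3]
coupling:
  - [0.0, 0.0, -0.5]
  - [0.8, 0.0, 0.0]
  - [0.0, 0.9, 0.0]
degradation: [0.6, 0.7, 0.5]
response:
  - [identity, identity, identity]
  - [sigmoid, identity, identity]
  - [identity, sigmoid, identity]
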