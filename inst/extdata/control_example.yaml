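# Regulation targets for the linear two-gland cascade fixture.
targets: [0.8, 1.2]
weights: [1.0, 1.0]
intervention_lr: 0.5
decay: 0.05
max_iters: 50
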