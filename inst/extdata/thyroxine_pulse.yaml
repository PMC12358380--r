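# One thyroxine replacement pulse: dose 0.4 on the T3 pool over t in [1, 3].
glands: [TRH, TSH, T3]
pulses:
  - {target: T3, dose: 0.4, start: 1.0, end: 3.0}
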