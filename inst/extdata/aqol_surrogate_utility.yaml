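name: aqol_surrogate_multiplicative
weights:
  independent_living: 0.5
  relationships: 0.45
  mental_health: 0.65
  coping: 0.55
  pain: 0.6
  senses: 0.3
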