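name: CsCl pipette solution (high chloride)
temperature_C: 29
salts:
  CsCl: 150
  EGTA: 5
  MgCl2: 1
  HEPES: 10
  ATP: 2
  GTP: 0.3
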