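name: CsMeSO4 pipette solution (low chloride)
temperature_C: 29
salts:
  CsMeSO4: 135
  HEPES: 12
  NaCl: 8
  EGTA: 0.25
  MgCl2: 2
  ATP: 2
  GTP: 0.3
  phosphocreatine: 5
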