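name: recording ACSF
temperature_C: 29
salts:
  NaCl: 125
  KCl: 2.5
  glucose: 25
  NaHCO3: 25
  NaH2PO4: 1.25
  MgCl2: 1
  CaCl2: 2
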