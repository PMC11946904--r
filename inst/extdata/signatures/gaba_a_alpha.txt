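GABRA1
GABRA2
GABRA3
GABRA4
GABRA5
GABRA6
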