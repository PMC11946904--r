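GABRA1
GABRA2
GABRA3
GABRA4
GABRA5
GABRA6
GABRB1
GABRB2
GABRB3
GABRG1
GABRG2
GABRG3
GABRD
GABRE
GABRP
GABRQ
GABRR1
GABRR2
GABRR3
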