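dilution	replicate	call	molecular_copies
D1	R1	detected	549
D1	R2	detected	652
D2	R1	detected	272
D2	R2	detected	321
D2	R3	detected	287
D3	R1	detected	158
D3	R2	detected	171
D3	R3	detected	141
D4	R1	detected	66
D4	R2	detected	98
D4	R3	detected	81
D5	R1	detected	49
D5	R2	detected	46
D5	R3	detected	31
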