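dilution	replicate	call	fold_change
D1	R1	detected	5.64
D1	R2	detected	5.08
D2	R1	detected	2.27
D2	R2	detected	2.35
D2	R3	detected	2.27
D3	R1	detected	1.4
D3	R2	detected	1.42
D3	R3	detected	1.38
D4	R1	not_detected	NA
D4	R2	not_detected	NA
D4	R3	not_detected	NA
D5	R1	not_detected	NA
D5	R2	not_detected	NA
D5	R3	not_detected	NA
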