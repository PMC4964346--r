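temperature_C	diffusivity_1e3mm2s
15	0.400
18	0.427
20	0.445
22	0.464
25	0.492
28	0.521
30	0.541
35	0.592
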