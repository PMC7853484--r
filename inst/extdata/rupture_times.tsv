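species_code	optimal_bead_mm	t95_s
AC	1.4	112
AG	2.8	605
BN	1.4	249
CA	2.8	493
CS	1.4	231
DG	1.4	325
Pic	2.8	211
PL	2.8	502
Pop	1.4	66
RA	1.4	123
SC	1.4	482
TB	1.4	69
TP	5.0	323
UG	2.8	660
ZM	5.0	114
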