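marker	species_code	present
rbcL_aF_r506	AC	1
rbcL_aF_r506	AG	1
rbcL_aF_r506	BN	1
rbcL_aF_r506	CA	1
rbcL_aF_r506	DG	1
rbcL_aF_r506	Pic	1
rbcL_aF_r506	PL	1
rbcL_aF_r506	Pop	1
rbcL_aF_r506	RA	1
rbcL_aF_r506	SC	1
rbcL_aF_r506	TB	0
rbcL_aF_r506	TP	1
rbcL_aF_r506	UG	1
rbcL_aF_r506	ZM	0
rbcL_2_aR	AC	1
rbcL_2_aR	AG	0
rbcL_2_aR	BN	0
rbcL_2_aR	CA	0
rbcL_2_aR	DG	0
rbcL_2_aR	Pic	1
rbcL_2_aR	PL	0
rbcL_2_aR	Pop	1
rbcL_2_aR	RA	0
rbcL_2_aR	SC	1
rbcL_2_aR	TB	1
rbcL_2_aR	TP	0
rbcL_2_aR	UG	0
rbcL_2_aR	ZM	0
ITS1	AC	0
ITS1	AG	1
ITS1	BN	1
ITS1	CA	1
ITS1	DG	1
ITS1	Pic	0
ITS1	PL	1
ITS1	Pop	1
ITS1	RA	1
ITS1	SC	1
ITS1	TB	0
ITS1	TP	0
ITS1	UG	1
ITS1	ZM	0
ITS2_universal	AC	1
ITS2_universal	AG	1
ITS2_universal	BN	1
ITS2_universal	CA	1
ITS2_universal	DG	1
ITS2_universal	Pic	1
ITS2_universal	PL	1
ITS2_universal	Pop	1
ITS2_universal	RA	1
ITS2_universal	SC	1
ITS2_universal	TB	1
ITS2_universal	TP	1
ITS2_universal	UG	1
ITS2_universal	ZM	0
ITS2_plant	AC	1
ITS2_plant	AG	1
ITS2_plant	BN	1
ITS2_plant	CA	1
ITS2_plant	DG	1
ITS2_plant	Pic	1
ITS2_plant	PL	1
ITS2_plant	Pop	1
ITS2_plant	RA	1
ITS2_plant	SC	1
ITS2_plant	TB	1
ITS2_plant	TP	1
ITS2_plant	UG	1
ITS2_plant	ZM	0
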