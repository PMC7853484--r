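marker	treatment_code	replicate	D
rbcL_aF_r506	0	1	1.2094
rbcL_aF_r506	0	2	1.2536
rbcL_aF_r506	0	3	1.2436
rbcL_aF_r506	33	1	1.3201
rbcL_aF_r506	33	2	1.2346
rbcL_aF_r506	33	3	1.2376
rbcL_aF_r506	67	1	1.0824
rbcL_aF_r506	67	2	1.0136
rbcL_aF_r506	67	3	1.0129
rbcL_aF_r506	100	1	1.2538
rbcL_aF_r506	100	2	1.2362
rbcL_aF_r506	100	3	1.2105
ITS2_universal	0	1	1.0274
ITS2_universal	0	2	1.0899
ITS2_universal	0	3	1.1689
ITS2_universal	33	1	0.9335
ITS2_universal	33	2	0.9686
ITS2_universal	33	3	0.9604
ITS2_universal	67	1	1.1533
ITS2_universal	67	2	1.0824
ITS2_universal	67	3	1.0132
ITS2_universal	100	1	1.0628
ITS2_universal	100	2	1.0914
ITS2_universal	100	3	1.0806
ITS2_plant	0	1	0.9779
ITS2_plant	0	2	0.9738
ITS2_plant	0	3	0.9291
ITS2_plant	33	1	0.6455
ITS2_plant	33	2	0.6748
ITS2_plant	33	3	0.6386
ITS2_plant	67	1	0.7216
ITS2_plant	67	2	0.7411
ITS2_plant	67	3	0.8588
ITS2_plant	100	1	0.8197
ITS2_plant	100	2	0.7846
ITS2_plant	100	3	0.7803
ITS1	0	1	0.9477
ITS1	0	2	0.9676
ITS1	0	3	0.9564
ITS1	33	1	1.0137
ITS1	33	2	1.1108
ITS1	33	3	1.0407
ITS1	67	1	0.9418
ITS1	67	2	0.9837
ITS1	67	3	0.9612
ITS1	100	1	1.444
ITS1	100	2	1.4611
ITS1	100	3	1.3872
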