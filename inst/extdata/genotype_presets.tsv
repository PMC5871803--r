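name	nFirstOrder	elongationRate	interLateralDistance	insertionAngleMean	insertionAngleSd	gravitropism	headingNoiseSd	maxOrder	diameterBase	diameterRatioLateral	duration	step
mock	3	1.5	0.8	60	8	0.10	0.12	3	0.10	0.5	10	0.5
slow	3	0.9	0.8	60	8	0.10	0.12	3	0.10	0.5	10	0.5
fast	3	2.2	0.8	60	8	0.10	0.12	3	0.10	0.5	10	0.5
dense	3	1.5	0.4	60	8	0.10	0.12	3	0.10	0.5	10	0.5
sparse	3	1.5	1.6	60	8	0.10	0.12	3	0.10	0.5	10	0.5
steep	3	1.5	0.8	60	8	0.30	0.12	3	0.10	0.5	10	0.5
shallow	3	1.5	0.8	60	8	0.02	0.12	3	0.10	0.5	10	0.5
fibrous	10	1.2	1.2	60	8	0.10	0.12	2	0.07	0.5	10	0.5
taproot	1	2.5	0.5	60	8	0.10	0.12	3	0.15	0.5	10	0.5
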