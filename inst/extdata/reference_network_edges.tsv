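source	target	linear_coef	nonlinear_coef
2	1	0.7	0.5
3	1	0.7	0.5
3	2	0.7	0.5
3	4	0.7	0.5
3	5	0.7	0.5
4	2	0.7	0.5
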