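method	train_timepoint	test_timepoint	tp	fn	tn	fp	sens_pct	spec_pct
plsda	1	NA	3	2	3	3	60	50
plsda	2	NA	5	0	6	0	100	100
plsda	3	NA	5	0	6	0	100	100
plsda	4	NA	5	0	6	0	100	100
plsda	5	NA	5	0	5	1	100	83.33
rf	1	NA	2	3	2	4	40	66.67
rf	2	NA	4	1	6	0	80	100
rf	3	NA	5	0	5	1	100	83.33
rf	4	NA	5	0	6	0	100	100
rf	5	NA	5	0	5	1	100	83.33
plsda	2	2	4	0	4	0	100	100
plsda	4	3	0	4	3	1	0	75
plsda	5	4	4	0	2	2	100	50
rf	2	2	3	1	3	1	75	75
rf	4	3	0	4	2	2	0	50
rf	5	4	3	1	3	1	75	75
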