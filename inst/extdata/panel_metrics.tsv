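metabolite	timepoint	mda_pct	vip	auc
tryptophan	2	1.20	1.7	1.0
taurine	2	1.19	1.6	1.0
threonic acid	2	1.11	1.5	1.0
tyrosine	2	0.36	1.4	0.93
lyxitol	2	0.23	1.4	0.93
xylitol	2	0.38	1.4	0.93
pseudouridine	2	0.35	1.3	0.9
tryptophan	3	0.52	1.6	0.9
taurine	3	1.21	2.0	1.0
threonic acid	3	0.00	1.3	0.9
tyrosine	3	0.17	1.6	0.93
lyxitol	3	1.15	1.9	1.0
xylitol	3	0.16	1.2	0.97
pseudouridine	3	1.77	1.9	1.0
tryptophan	4	0.44	1.5	0.97
taurine	4	0.46	1.4	0.93
threonic acid	4	0.61	1.4	0.97
tyrosine	4	1.31	1.8	1.0
lyxitol	4	1.47	1.6	1.0
xylitol	4	0.52	1.5	0.93
pseudouridine	4	0.31	1.2	0.93
tryptophan	5	-0.07	1.2	0.9
taurine	5	0.40	1.5	0.93
threonic acid	5	-0.23	1.3	0.87
tyrosine	5	2.85	2.1	1.0
lyxitol	5	0.33	1.5	0.9
xylitol	5	0.08	1.4	0.87
pseudouridine	5	0.58	1.6	0.9
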