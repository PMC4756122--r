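assay	slope	intercept	efficiency_printed	roq_min	roq_max	lod
Av4143	3.75	44.05	84.7	25	2.5e8	6
Av163	3.3	40.9	100	18	3.6e8	9
Av43	3.39	41.4	97	25	2.5e8	6
Av216	3.4	40.5	96.8	24	2.4e8	6
Av24	3.4	40.1	96.8	20	2.0e8	5
Av13	3.43	42.3	95.6	19	3.8e8	8
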