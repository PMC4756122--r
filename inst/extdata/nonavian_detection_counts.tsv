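assay	host_group	n_samples	n_positive
Av4143	wastewater	25	1
Av4143	bovine	40	0
Av4143	swine	20	1
Av4143	horse	9	1
Av4143	gazelle	10	0
Av163	wastewater	25	0
Av163	bovine	40	15
Av163	swine	20	0
Av163	horse	9	0
Av163	gazelle	10	0
Av43	wastewater	25	0
Av43	bovine	40	1
Av43	swine	20	0
Av43	horse	9	0
Av43	gazelle	10	0
Av216	wastewater	25	0
Av216	bovine	40	1
Av216	swine	20	0
Av216	horse	9	0
Av216	gazelle	10	0
Av24	wastewater	25	0
Av24	bovine	40	0
Av24	swine	20	0
Av24	horse	9	0
Av24	gazelle	10	0
Av13	wastewater	25	0
Av13	bovine	40	0
Av13	swine	20	0
Av13	horse	9	0
Av13	gazelle	10	0
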