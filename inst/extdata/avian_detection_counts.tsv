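assay	host_group	n_samples	n_positive
Av4143	battery_hen	50	48
Av4143	poultry	20	18
Av4143	turkey	10	10
Av4143	waterfowl	17	14
Av163	battery_hen	50	48
Av163	poultry	20	10
Av163	turkey	10	0
Av163	waterfowl	17	10
Av43	battery_hen	50	46
Av43	poultry	20	18
Av43	turkey	10	1
Av43	waterfowl	17	1
Av216	battery_hen	50	0
Av216	poultry	20	0
Av216	turkey	10	0
Av216	waterfowl	17	13
Av24	battery_hen	50	0
Av24	poultry	20	0
Av24	turkey	10	0
Av24	waterfowl	17	9
Av13	battery_hen	50	0
Av13	poultry	20	0
Av13	turkey	10	0
Av13	waterfowl	17	8
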