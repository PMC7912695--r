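site	mat	map	ph	p	n	c
ARG	19.2	319	6.40	11.40	0.03	0.60
AUS	22.4	278	4.90	61.00	0.03	0.29
ISR	17.1	113	7.47	0.38	0.09	0.62
KAZ	10.6	192	7.59	1.98	0.03	0.42
SAU	25.9	105	8.50	22.60	0.10	0.45
USA	21.2	141	7.35	6.51	0.05	0.37
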