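scale	site	z
global	ARG	1.560
global	AUS	1.337
global	ISR	1.612
global	KAZ	1.551
global	SAU	-0.406
global	USA	-0.331
continent	ARG	3.217
continent	AUS	3.088
continent	ISR	2.970
continent	KAZ	2.427
continent	SAU	-0.554
continent	USA	-0.166
realm	ARG	3.251
realm	AUS	3.180
realm	ISR	1.254
realm	KAZ	1.417
realm	SAU	-0.447
realm	USA	-0.152
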