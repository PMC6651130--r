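pair1	AU	UA	GC	CG	GU	UG
AU	-0.93	-1.10	-2.08	-2.24	-0.55	-1.36
UA	-1.33	-0.93	-2.11	-2.35	-1.27	-1.00
GC	-2.35	-2.24	-3.26	-3.42	-1.80	-2.11
CG	-2.11	-2.08	-2.36	-3.26	-1.41	-1.53
GU	-1.00	-1.36	-1.53	-2.11	-0.50	0.47
UG	-1.27	-0.55	-1.41	-1.80	0.30	-0.50
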