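sample	condition	context	n_sites	n_methylated
WT1	WT	CG	8335974	3193016
WT1	WT	CHG	11664623	2275905
WT1	WT	CHH	62367490	3833891
WT2	WT	CG	8335974	3153580
WT2	WT	CHG	11664623	2396865
WT2	WT	CHH	62367490	6156465
WT3	WT	CG	8335974	3015038
WT3	WT	CHG	11664623	2258108
WT3	WT	CHH	62367490	5709047
RT1	RT	CG	8335974	3086648
RT1	RT	CHG	11664623	2350640
RT1	RT	CHH	62367490	6171940
RT2	RT	CG	8335974	3170368
RT2	RT	CHG	11664623	2434099
RT2	RT	CHH	62367490	6386536
RT3	RT	CG	8335974	3411185
RT3	RT	CHG	11664623	2580335
RT3	RT	CHH	62367490	6231272
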