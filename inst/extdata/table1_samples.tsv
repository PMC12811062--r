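sample_id	condition	nitrogen	replicate	timepoint	od_t1	od_t2	d	mapped_reads
acetate_rep1	acetate	diazotrophic	1	t2	0.0500413	6.06	121.1	15001388
acetate_rep2	acetate	diazotrophic	2	t2	0.0500507	4.94	98.7	16871019
succinate_rep1	succinate	diazotrophic	1	t2	0.0500000	6.00	120.0	17650273
succinate_rep2	succinate	diazotrophic	2	t2	0.0499676	7.70	154.1	15571966
glycerol_rep1	glycerol	diazotrophic	1	t2	0.0500000	6.75	135.0	18910633
glycerol_rep2	glycerol	diazotrophic	2	t2	0.0499631	6.77	135.5	16842781
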