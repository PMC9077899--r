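comparison	total	both_deg	ratio_significant	doubly_significant	tf_tr_up	tf_tr_down	tf_up_tr_down	tf_down_tr_up
LUAD_vs_NORMAL	1972	1497	1019	813	89	128	98	498
LUSC_vs_NORMAL	4037	2917	3036	2229	533	479	618	599
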