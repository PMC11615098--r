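allele_key	region_name	start	end
IGHV1-2*01	leader1	1	46
IGHV1-2*01	intron	47	133
IGHV1-2*01	leader2	134	144
IGHV1-2*01	v_region	145	440
IGHV1-2*01	rss	441	479
IGHV1-2*02	leader1	1	46
IGHV1-2*02	intron	47	133
IGHV1-2*02	leader2	134	144
IGHV1-2*02	v_region	145	440
IGHV1-2*02	rss	441	479
IGHV6-1*01	leader1	1	46
IGHV6-1*01	intron	47	140
IGHV6-1*01	leader2	141	151
IGHV6-1*01	v_region	152	447
IGHV6-1*01	rss	448	486
IGHV6-1*02	leader1	1	46
IGHV6-1*02	intron	47	140
IGHV6-1*02	leader2	141	151
IGHV6-1*02	v_region	152	447
IGHV6-1*02	rss	448	486
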