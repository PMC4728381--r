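element	total_bases	tag_count	tags_per_kb_published
CDS_Exons	17597397	10651	0.61
Introns	17376020	4652	0.27
TSS_up_1kb	12615965	1012	0.08
TSS_up_5kb	35083848	2304	0.07
TSS_up_10kb	57615402	2585	0.04
TES_down_1kb	11356574	1191	0.10
TES_down_5kb	31789833	2351	0.07
TES_down_10kb	53166077	2506	0.05
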