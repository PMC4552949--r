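group	TE	DUP	BOTH	group_total
SSG	374	355	107	1423
GSG	1588	2527	887	4539
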