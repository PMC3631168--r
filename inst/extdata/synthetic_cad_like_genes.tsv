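LRP5L_s1	LRP5L
LRP5L_s2	LRP5L
LRP6L_s1	LRP6L
LRP6L_s2	LRP6L
LRP6L_s3	LRP6L
LRP6L_s4	LRP6L
LRP6L_s5	LRP6L
LRP6L_s6	LRP6L
LRP6L_s7	LRP6L
LRP6L_s8	LRP6L
LRP6L_s9	LRP6L
PCSK9L_s1	PCSK9L
PCSK9L_s2	PCSK9L
PCSK9L_s3	PCSK9L
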