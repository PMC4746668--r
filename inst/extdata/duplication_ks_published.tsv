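gene1	gene2	ks
GaTCP2	GaTCP24	0.3869
GaTCP3	GaTCP10	0.3868
GaTCP10	GaTCP4	0.4783
GaTCP7a	GaTCP7b	0.5899
GaTCP9b	GaTCP19b	0.4529
GaTCP13b	GaTCP13a	0.6527
GaTCP14b	GaTCP14c	0.5637
GaTCP15a	GaTCP15b	0.6751
GaTCP17	GaTCP5	1.0293
GaTCP18a	GaTCP18b	1.0954
GaTCP20a	GaTCP20d	0.4212
GaTCP20c	GaTCP6	0.3384
GaTCP20b	GaTCP20a	0.4097
GaTCP20d	GaTCP20b	0.4599
GaTCP22	GaTCP8	0.9276
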