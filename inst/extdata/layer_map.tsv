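chain	layer	residue
syb	-7	32
syb	-6	35
syb	-5	38
syb	-4	42
syb	-3	45
syb	-2	49
syb	-1	52
syb	0	56
syb	1	60
syb	2	63
syb	3	67
syb	4	70
syb	5	74
syb	6	77
syb	7	81
syb	8	84
syx	-7	202
syx	-6	205
syx	-5	208
syx	-4	212
syx	-3	215
syx	-2	219
syx	-1	222
syx	0	226
syx	1	230
syx	2	233
syx	3	237
syx	4	240
syx	5	244
syx	6	247
syx	7	251
syx	8	254
snap25n	-7	29
snap25n	-6	32
snap25n	-5	35
snap25n	-4	39
snap25n	-3	42
snap25n	-2	46
snap25n	-1	49
snap25n	0	53
snap25n	1	57
snap25n	2	60
snap25n	3	64
snap25n	4	67
snap25n	5	71
snap25n	6	74
snap25n	7	78
snap25n	8	81
snap25c	-7	150
snap25c	-6	153
snap25c	-5	156
snap25c	-4	160
snap25c	-3	163
snap25c	-2	167
snap25c	-1	170
snap25c	0	174
snap25c	1	178
snap25c	2	181
snap25c	3	185
snap25c	4	188
snap25c	5	192
snap25c	6	195
snap25c	7	199
snap25c	8	202
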