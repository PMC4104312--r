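name	pattern	rank	hc_group	phospho
L1	GKEVDA	1		FALSE
HC1	FAPERSGXLIQE	2	HC1	FALSE
R1	TPRXS[SN]	3	HC2	TRUE
R2	SNAWGE	4	HC2	FALSE
R3	DKLYGQ	5	HC2	FALSE
L2	WEQNKE	6		FALSE
HC3	YSLQESNPGXME	7	HC3	FALSE
L3	PKDQFS	8		FALSE
HC4	NKDLHMFVWSSK	9	HC4	FALSE
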