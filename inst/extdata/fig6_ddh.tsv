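# Digital DNA-DNA hybridization (dDDH) panel for the genus survey.
# Values printed in the source only as bounds are encoded as representative
# numbers on the correct side of the 70% species cut-off and are approximate:
# ">90" -> 91, "~90" -> 90, "<70" -> 64/69 as attributed, "74-94" chain.
# The 33.5-33.8% relatedness of TP-A0468 to its three MLSA neighbours was
# reported without per-pair attribution; the midpoint is stored against all
# three (approximate).
strain_a	strain_b	metric	value
Micromonospora sp. B006	M. tulbaghiae DSM 45142	dDDH	51
Micromonospora sp. L5	M. aurantiaca ATCC 27029	dDDH	91
Micromonospora sp. RV43	M. aurantiaca ATCC 27029	dDDH	91
Micromonospora sp. WMMB235	M. aurantiaca ATCC 27029	dDDH	91
Micromonospora sp. CNZ297	M. aurantiaca ATCC 27029	dDDH	91
Micromonospora sp. CNZ296	M. aurantiaca ATCC 27029	dDDH	91
M. globosa NRRL B-2673	M. aurantiaca ATCC 27029	dDDH	91
Micromonospora sp. M42	M. chalcea DSM 43026	dDDH	90
Micromonospora sp. DSW705	M. chalcea DSM 43026	dDDH	90
Micromonospora sp. TSRI0369	M. chalcea DSM 43026	dDDH	64
Micromonospora sp. DSW705	Micromonospora sp. TSRI0369	dDDH	64
Micromonospora sp. WMMA2032	M. sediminicola DSM 45794	dDDH	37
M. parva NRRL B-2680	M. chokoriensis NRRL B-24750	dDDH	69
M. saelicesensis DSM 44871	Micromonospora sp. CNZ322	dDDH	71
Micromonospora sp. NRRL B-16802	M. profundi DSM 45981	dDDH	94
Micromonospora sp. TP-A0316	M. haikouensis JXNU-1	dDDH	94
M. haikouensis JXNU-1	M. haikouensis DSM 45626	dDDH	84
M. haikouensis DSM 45626	Micromonospora sp. Rc5	dDDH	74
Micromonospora sp. NRRL B-2672	M. purpureochromogenes DSM 43827	dDDH	27
Micromonospora sp. TP-A0468	M. haikouensis DSM 45626	dDDH	33.6
Micromonospora sp. TP-A0468	Micromonospora sp. TP-A0316	dDDH	33.6
Micromonospora sp. TP-A0468	M. carbonacea DSM 43168	dDDH	33.6
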