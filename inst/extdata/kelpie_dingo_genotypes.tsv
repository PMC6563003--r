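sample_id	population	declared_coat	declared_ears	MC1R_ginger	MC1R_mask	TYRP1_C41S	TYRP1_Y185X	TYRP1_Q331X	TYRP1_345delP	CBD103_K	MITF_SINE	MITF_length	RALY_dup	ASIP_ins239	ASIP_A82	ASIP_R83	ASIP_R92	MSRB3_UTR_ins	MSRB3_HMGA2_SNP
Dingo_RKW13760	Dingo		Prick	G/G	T/T	T/T	T/T	C/C	ins/ins	ins/ins	ins/ins	11C10A2G12A/11C10A2G12A	del/del	del/del	T/T	A/A	C/C	insTTTAT/insTTTAT	T/T
USCF305	AK	Brown	Prick	G/A	T/T	T/T	T/T	T/T	ins/ins	del/del	del/del	10C9A2G12A/10C9A2G12A	ins/ins	ins/ins	G/G	G/G	C/C	insTTTATTTTAT/insTTTATTTTAT	T/T
USCF6182	Kelpie_unspecified			G/G	T/T	T/T	T/T	T/T	ins/ins	ins/ins	del/del	10C9A2G12A/10C9A2G12A	ins/ins	ins/ins	G/G	G/G	C/C	insTTTATTTTAT/insTTTATTTTAT	T/T
USCF6203	Kelpie_unspecified			0 0	T/T	T/T	T/T	T/T	ins/ins	ins/ins	del/del	10C9A2G12A/10C9A2G12A	ins/ins	ins/ins	G/G	G/G	C/C	insTTTATTTTAT/insTTTATTTTAT	T/T
USCF634	AWK	Black and Tan		G/A	C/T	T/T	T/T	C/C	ins/ins	ins/ins	del/del	10C9A2G12A/10C9A2G12A	ins/ins	ins/ins	G/G	G/G	C/C	insTTTATTTTAT/insTTTATTTTAT†	C/T
USCF6343	Kelpie_unspecified			G/A	T/T	T/T	T/T	C/C	ins/ins	ins/ins	del/del	10C9A2G12A/10C9A2G12A	ins/ins	ins/ins	G/G	G/G	C/C	insTTTATTTTAT/insTTTATTTTAT	T/T
USCF635	AWK	Black and Tan		G/G	C/C	T/T	T/T	C/T	ins/ins	ins/ins	del/del	10C9A2G12A/10C9A2G12A	ins/ins	ins/ins	G/G	G/G	C/C	insTTTATTTTAT/insTTTATTTTAT	T/T
USCF636	AWK	Black and Tan		0 0	T/T	T/T	T/T	C/T	ins/ins	ins/ins	del/del	10C9A2G12A/10C9A2G12A	ins/ins	ins/ins	G/G	G/G	C/C	insTTTATTTTAT/insTTTATTTTAT	T/T
USCF639	AWK	Black and Tan		G/G	C/C	T/T	T/T	0 0	ins/ins	ins/ins	del/del	10C9A2G12A/10C9A2G12A	ins/ins	ins/ins	G/G	G/G	C/C	insTTTATTTTAT/insTTTATTTTAT	T/T
USCF640	AWK	Black and Tan		G/G	C/C	T/T	T/T	C/C	ins/ins	ins/ins	del/del	10C9A2G12A/10C8A2G11A	ins/ins	ins/ins	G/G	G/G	C/C	insTTTATTTTAT/insTTTATTTTAT	T/T
USCF6348	AWK			G/G	T/T	T/T	T/T	C/T	ins/ins	ins/ins	del/del	10C9A2G12A/10C9A2G12A	ins/ins	ins/ins	G/G	G/G	C/C	insTTTATTTTAT/insTTTATTTTAT	T/T
USCF6350	AWK			G/G	T/T	T/T	T/T	T/T	ins/ins	ins/ins	del/del	10C9A2G12A/10C9A2G12A	ins/ins	ins/ins	G/G	G/G	C/C	insTTTATTTTAT/insTTTATTTTAT	T/T
USCF6359	AWK	Brown and Tan	Prick	G/G	T/T	T/T	T/T	T/T	ins/ins	ins/ins	del/del	10C9A2G12A/10C9A2G12A	ins/ins	ins/ins	G/G	G/G	C/C	insTTTATTTTAT/insTTTATTTTAT	T/T
Labrador_LA882	Labrador		Drop	0 0	0 0	0 0	0 0	0 0	0 0	0 0	0 0	0 0	0 0	0 0	0 0	0 0	0 0	del/del	C/C
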