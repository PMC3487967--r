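reaction	rate_param	factors	mm_species	mm_k	stoich
bind	k1	TGFa:1,EGFR:1			TGFa:-1,EGFR:-1,Cplx:1
unbind	ku	Cplx:1			TGFa:1,EGFR:1,Cplx:-1
phos	k2	Cplx:2			Cplx:-2,pEGFR:2
dephos	V4		pEGFR	K4	pEGFR:-1,EGFR:1,TGFa:1
plc_act	k3	pEGFR:1,PLCgi:1			PLCgi:-1,PLCg:1
plc_rel	k5	PLCg:1			PLCg:-1,PLCgi:1
growth	kg	Mass:1			Mass:1
crowding	kg2	Mass:2			Mass:-1
cdk_syn	kc1	Mass:1			cycCDK:1
cdk_deg	kc2	cycCDK:1			cycCDK:-1
cdk_deg_cdh1	kc2p	CDh1:1,cycCDK:1			cycCDK:-1
cdh1_act	kc3		CDh1i	J3	CDh1i:-1,CDh1:1
cdh1_inact	kc4	cycCDK:1	CDh1	J4	CDh1:-1,CDh1i:1
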