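TLSRG	all 23 TLS-related genes	CCL18	CCL19	CCL20	CCL21	CXCL9	CXCL13	CCR5	CXCR3	IL10	CSF2	CD200	GFI1	IRF4	STAT5A	ICOS	CD38	CD40	SH2D1A	TIGIT	PDCD1	IL2RA	IL1R2	FBLN7
TLSRG_chemokine	chemokines	CCL18	CCL19	CCL20	CCL21	CXCL9	CXCL13
TLSRG_chemokine_receptor	chemokine receptors	CCR5	CXCR3
TLSRG_cytokine	cytokines	IL10	CSF2
TLSRG_transcription_factor	transcription factors	CD200	GFI1	IRF4	STAT5A
TLSRG_costimulatory	co-stimulatory molecules	ICOS	CD38	CD40	SH2D1A
TLSRG_inhibitory_receptor	inhibitory receptors	TIGIT	PDCD1
TLSRG_cytokine_receptor	cytokine receptors	IL2RA	IL1R2
TLSRG_ecm	ECM-associated molecule	FBLN7
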