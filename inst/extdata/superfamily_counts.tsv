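category	signature_id	signature_name	Tco	Tci	Cs	Aa	Ha	Nt	Os	At
Biodefense	IPR036041	Ribosome-inactivating protein	159	98	7	16	0	0	17	0
Metabolism	IPR005848	Urease, alpha subunit	108	15	1	3	1	7	0	1
Metabolism	IPR036226	Lipoxygenase, C-terminal domain	232	86	51	32	25	36	13	7
Metabolism	IPR033966	RuBisCO	42	8	11	9	1	3	8	2
Metabolism	IPR032466	Metal-dependent hydrolase	166	94	23	28	44	54	15	26
Metabolism	IPR036849	Enolase-like, C-terminal domain	71	50	14	15	12	19	6	7
Metabolism	IPR036396	Cytochrome P450	1220	745	732	688	568	600	314	361
Signaling	IPR035983	HECT, E3 ligase catalytic domain	95	72	41	25	18	32	7	13
Signaling	IPR039512	RCHY1, zinc-ribbon	3	8	12	12	13	39	6	12
Biodefense	IPR035992	Ricin B-like lectins	44	69	17	22	7	11	8	5
Biodefense	IPR036861	Endochitinase-like	7	1	5	6	14	11	9	12
Signaling	IPR036097	Signal transduction histidine kinase, dimerization/phosphoacceptor domain	32	101	21	26	28	46	7	19
Signaling	IPR024792	Rho GDP-dissociation inhibitor domain	18	34	10	6	8	10	3	3
Metabolism	IPR012347	Ferritin-like	22	35	11	5	6	4	2	6
Metabolism	IPR036909	Cytochrome c-like domain	21	39	9	6	12	17	7	7
Metabolism	IPR037069	Acyl-CoA dehydrogenase/oxidase, N-terminal domain	22	36	8	11	12	18	5	6
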