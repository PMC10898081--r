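exon	hgvs_c	hgvs_p	ag	al	dg	dl	ag_pos	al_pos	dg_pos	dl_pos	phase
1	c.9A>C	p.Val3=	0.00	0.00	0.04	0.55				3	prospective
1	c.9A>G	p.Val3=	0.00	0.00	0.04	0.54				3	prospective
1	c.9A>T	p.Val3=	0.00	0.00	0.04	0.55				3	prospective
1	c.11C>G	p.Thr4Arg	0.00	0.00	0.44	0.45			5	-44	prospective
1	c.15C>T	p.Gly5=	0.00	0.00	0.52	0.13			2	-40	prospective
1	c.26T>G	p.Leu9Arg	0.00	0.00	0.03	0.29				20	retrospective
1	c.29G>A	p.Ser10Asn	0.00	0.00	0.11	0.03			23		retrospective
1	c.36G>C	p.Leu12Phe	0.00	0.00	0.02	0.10				30	retrospective
1	c.41T>C	p.Leu14Pro	0.00	0.00	0.01	0.04					retrospective
1	c.41T>G	p.Leu14Arg	0.00	0.00	0.02	0.09				35	retrospective
1	c.43T>A	p.Leu15Met	0.00	0.00	0.02	0.12				37	prospective
1	c.43T>C	p.Leu15=	0.00	0.00	0.03	0.14				37	prospective
1	c.43T>G	p.Leu15Val	0.00	0.00	0.38	0.00			1		prospective
1	c.55G>A	p.Gly19Ser	0.00	0.00	0.36	0.40			49	0	prospective
1	c.55G>C	p.Gly19Arg	0.00	0.00	0.33	0.34			49	0	prospective
1	c.55G>T	p.Gly19Cys	0.00	0.00	0.37	0.51			49	0	prospective
2	c.56G>A	p.Gly19Asp	0.01	0.10	0.00	0.07		0			prospective
2	c.56G>C	p.Gly19Ala	0.01	0.40	0.00	0.29		0		-31	prospective
2	c.56G>T	p.Gly19Val	0.01	0.61	0.00	0.46		0		-31	prospective
2	c.65G>T	p.Gly22Val	0.00	0.31	0.00	0.17		9		-22	prospective
2	c.75C>T	p.Ser25=	0.00	0.02	0.00	0.02					retrospective
2	c.80G>T	p.Gly27Val	0.00	0.09	0.61	0.10			2	-7	prospective
2	c.84A>C	p.Arg28Ser	0.00	0.01	0.00	0.00					prospective
2	c.84A>G	p.Arg28=	0.00	0.49	0.00	0.25		28		-3	prospective
2	c.84A>T	p.Arg28Ser	0.00	0.04	0.01	0.02					prospective
2	c.85G>T	p.Glu29*	0.00	0.25	0.00	0.17		29		-2	prospective
2	c.86A>C	p.Glu29Ala	0.00	0.51	0.01	0.23		30		-1	prospective
2	c.86A>G	p.Glu29Gly	0.00	0.84	0.00	0.67		30		-1	prospective
2	c.86A>T	p.Glu29Val	0.00	0.81	0.00	0.58		30		-1	prospective
2	c.87G>A	p.Glu29=	0.00	0.87	0.00	0.92		31		0	prospective
2	c.87G>C	p.Glu29Asp	0.00	0.84	0.01	0.93		31		0	prospective
2	c.87G>T	p.Glu29Asp	0.00	0.88	0.00	0.93		31		0	prospective
3	c.88G>A	p.Ala30Thr	0.00	0.00	0.00	0.00					prospective
3	c.88G>C	p.Ala30Pro	0.00	0.00	0.00	0.00					prospective
3	c.88G>T	p.Ala30Ser	0.00	0.01	0.00	0.00					prospective
3	c.101A>G	p.Asn34Ser	0.00	0.00	0.00	0.00					retrospective
3	c.110A>G	p.Asn37Ser	0.00	0.00	0.00	0.00					retrospective
3	c.123G>C	p.Lys41Asn	0.00	0.00	0.00	0.00					retrospective
3	c.126A>G	p.Ile42Met	0.00	0.00	0.00	0.00					retrospective
3	c.133C>T	p.Pro45Ser	0.00	0.00	0.00	0.00					retrospective
3	c.137T>A	p.Val46Asp	0.00	0.00	0.00	0.00					retrospective
3	c.143G>A	p.Gly48Glu	0.00	0.00	0.00	0.00					retrospective
3	c.150T>G	p.Asp50Glu	0.00	0.00	0.00	0.00					retrospective
3	c.160T>C	p.Tyr54His	0.00	0.00	0.00	0.00					retrospective
3	c.163C>T	p.Pro55Ser	0.00	0.00	0.00	0.00					retrospective
3	c.174C>T	p.Cys58=	0.00	0.00	0.00	0.00					retrospective
3	c.178T>G	p.Leu60Val	0.00	0.00	0.26	0.00			1		prospective
3	c.190A>G	p.Asn64Asp	0.00	0.00	0.00	0.00					retrospective
3	c.193C>T	p.Arg65Trp	0.00	0.00	0.00	0.00					retrospective
3	c.194G>A	p.Arg65Gln	0.00	0.00	0.00	0.00					retrospective
3	c.194G>C	p.Arg65Pro	0.00	0.00	0.00	0.00					prospective
3	c.194G>T	p.Arg65Leu	0.00	0.00	0.00	0.00					prospective
4	c.195G>A	p.Arg65=	0.00	0.03	0.00	0.00					prospective
4	c.195G>C	p.Arg65=	0.00	0.10	0.00	0.00		0			prospective
4	c.195G>T	p.Arg65=	0.00	0.23	0.00	0.00		0			prospective
4	c.198A>C	p.Lys66Asn	0.01	0.00	0.00	0.00					retrospective
4	c.199C>T	p.Arg67Cys	0.00	0.01	0.00	0.00					retrospective
4	c.200G>A	p.Arg67His	0.00	0.00	0.00	0.00					retrospective
4	c.203A>G	p.Gln68Arg	0.01	0.00	0.00	0.00					retrospective
4	c.206C>T	p.Thr69Ile	0.00	0.01	0.00	0.00					retrospective
4	c.231G>A	p.Gly77=	0.01	0.00	0.00	0.00					retrospective
4	c.236G>T	p.Cys79Phe	0.00	0.02	0.00	0.00					retrospective
1	c.29G>T	p.Ser10Ile	0.00	0.00	0.24	0.10			23	-26	validation
1	c.37G>T	p.Ala13Ser	0.00	0.00	0.23	0.08			31		validation
2	c.64G>T	p.Gly22*	0.00	0.22	0.00	0.11		8		-23	validation
2	c.81A>T	p.Gly27=	0.00	0.22	0.00	0.13		25		-6	validation
3	c.92A>G	p.Lys31Arg	0.13	0.00	0.00	0.00	-1				validation
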