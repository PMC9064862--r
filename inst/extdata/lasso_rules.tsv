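label	rule_id	domain_regex	desc_regex	min_bp	max_bp
B2	B2_domain	PF13471		300	600
B2	B2_desc		lasso peptide biosynthesis B2	300	600
B1	B1_domain	PF05402		150	400
B1	B1_desc		PqqD	150	400
C	C_domain	Asn_synthase		1500	2200
C	C_desc		asparagine synth	1500	2200
D	D_desc		ABC transporter	600	1200
D	D_domain	ABC.transporter		600	1200
A	A_domain	predicted lasso peptide		1	210
A	A_size_scan			1	210
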