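bgc	gene	size_bp	description	domain_tag	precursor_ok	published_label
40.1	8	975	Hypothetical protein	-	NA	none
40.1	9	1905	Hypothetical protein	Asn_synthase	NA	C
40.1	10	432	Hypothetical protein	-	NA	none
40.1	11	423	Lasso peptide biosynthesis B2 protein	PF13471	NA	B2
40.1	12	294	PqqD family peptide modification chaperone	PF05402	NA	B1
40.1	13	1116	Erythromycin biosynthesis sensory transduction protein eryC1	DegT_DnrJ_EryC1	NA	none
482.1	10.1	276	Hypothetical protein DMG37_22385	PF05402	NA	B1
482.1	10.2	276	PqqD family protein	-	NA	B1
482.1	11	1404	Aminoglycoside phosphotransferase family protein	-	NA	none
482.1	12	375	Lasso peptide biosynthesis B2 protein	PF13471	NA	B2
482.1	13	1929	Hypothetical protein	Asn_synthase	NA	C
482.1	14	141	Hypothetical protein	-	TRUE	A
482.1	15	141	Hypothetical protein	-	TRUE	A
482.1	16	2118	Hypothetical protein DMG78_32005	-	NA	none
44.1	8	822	ABC transporter permease	-	NA	D
44.1	9	810	ABC transporter ATP-binding protein	ABC transporter ATP-binding protein	NA	D
44.1	10	303	PqqD family peptide modification chaperone	PF05402	NA	B1
44.1	11	471	Lasso peptide biosynthesis B2 protein	PF13471	NA	B2
44.1	12	1863	Asparagine synthetase B	Asn_synthase	NA	C
44.1	13	150	Hypothetical protein DMG36_15005	Predicted lasso peptide	NA	A
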