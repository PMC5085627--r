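label	gene	region	change	ci_percent	n_case	n_control	zygosity
A1629T	tRNA-Val	rna	A-U pair abolished	24.4	1	0	homoplasmic
A2274G	16S-rRNA	rna	NA	100	1	0	heteroplasmic
3275-3276delCA	tRNA-Leu(UUR)	rna	NA	NA	1	0	heteroplasmic
T4272C	tRNA-Ile	rna	A-U pair abolished	100	1	0	homoplasmic
5835insT	tRNA-Tyr	rna	NA	NA	1	0	homoplasmic
G5881C	tRNA-Tyr	rna	C-G pair abolished	100	1	0	homoplasmic
C10040A	tRNA-Gly	rna	NA	43.9	1	0	homoplasmic
4520-4521delAC	ND2	protein	NA	NA	1	0	homoplasmic
C4875T	ND2	protein	Leu->Leu	100	1	0	homoplasmic
G4969A	ND2	protein	Trp->Ter	100	1	0	homoplasmic
G4971A	ND2	protein	Gly->Ser	100	1	0	homoplasmic
G5977A	COI	protein	Trp->Ter	100	1	0	heteroplasmic
T6238C	COI	protein	Leu->Pro	100	1	0	heteroplasmic
T7104C	COI	protein	Ser->Pro	100	1	0	heteroplasmic
C7750A	COII	protein	Ile->Met	58.5	1	0	homoplasmic
G7928A	COII	protein	Gly->Ter	56.1	1	0	homoplasmic
G9253A	COIII	protein	Trp->Ter	100	1	0	heteroplasmic
G10521A	ND4L	protein	Gly->Ter	100	1	0	homoplasmic
C10622T	ND4L	protein	Thr->Thr	36.6	1	0	homoplasmic
11646insT	ND4	protein	NA	NA	1	0	homoplasmic
11673-11677:C5-4	ND4	protein	NA	NA	1	0	heteroplasmic
11673-11677:C5-6	ND4	protein	NA	NA	1	0	homoplasmic
T12794A	ND5	protein	Leu->Ter	100	1	0	heteroplasmic
12858insT	ND5	protein	NA	NA	1	0	heteroplasmic
C12943T	ND5	protein	Leu->Phe	24.4	1	0	heteroplasmic
13128-13132:C5-4	ND5	protein	NA	NA	1	0	homoplasmic
13170delA	ND5	protein	NA	NA	1	0	homoplasmic
C13621T	ND5	protein	Leu->Phe	51.2	1	0	homoplasmic
G13825A	ND5	protein	Gly->Ter	100	1	0	homoplasmic
C14310A	ND6	protein	Gly->Trp	70.7	1	0	heteroplasmic
14495-14502:AAAT2-1	ND6	protein	NA	NA	1	0	homoplasmic
C14774A	Cytb	protein	Leu->Ile	63.4	1	0	heteroplasmic
T15018A	Cytb	protein	Phe->Tyr	100	1	0	heteroplasmic
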