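label	gene	aa_change	ci_percent	reported	n_case	n_thyroid	n_control	polyphen2	sift	mutation_assessor	provean	snp_and_go	align_gvgd	panther_pdel
G3392A	ND1	Gly->Asp	100	TRUE	1	0	0	Probably	NotTolerated	High	Deleterious	Disease	C65	NA
T3644C	ND1	Val->Ala	97.6	TRUE	1	0	2	Benign	NotTolerated	Medium	Deleterious	Neutral	C65	0.29125
T3679C	ND1	Ser->Pro	100	TRUE	1	0	0	Probably	NotTolerated	High	Deleterious	Disease	C65	0.74261
G3745A	ND1	Ala->Thr	92.7	TRUE	1	0	0	Benign	NotTolerated	Low	Neutral	Neutral	C55	0.21113
G4971A	ND2	Gly->Ser	100	FALSE	1	0	0	Probably	NotTolerated	Medium	Deleterious	Neutral	C55	0.36251
T6238C	COI	Leu->Pro	100	FALSE	1	0	0	Probably	NotTolerated	High	Deleterious	Disease	C65	0.87509
C6340T	COI	Thr->Ile	82.9	TRUE	1	0	0	Benign	NotTolerated	Medium	Neutral	Neutral	C65	0.21096
T6681C	COI	Tyr->His	85.4	TRUE	1	0	0	Benign	Tolerated	Neutral	Neutral	Neutral	C65	0.32881
T7104C	COI	Ser->Pro	100	FALSE	1	0	0	Possibly	NotTolerated	Neutral	Neutral	Disease	C65	0.5134
T7329C	COI	Phe->Leu	100	FALSE	1	0	0	Benign	Tolerated	Low	Neutral	Neutral	C15	0.16379
G8156A	COII	Val->Met	75.61	FALSE	1	0	0	Probably	NotTolerated	Medium	Neutral	Neutral	C15	0.53442
G8989A	ATP6	Ala->Thr	100	TRUE	1	0	0	Probably	NotTolerated	Low	Deleterious	Neutral	C55	0.47286
T9187C	ATP6	Tyr->His	100	TRUE	1	0	0	Probably	NotTolerated	High	Deleterious	Disease	C65	NA
A9355G	COIII	Asn->Ser	82.9	TRUE	1	0	0	Benign	Tolerated	Neutral	Neutral	Neutral	C45	0.14014
G10573A	ND4L	Gly->Glu	97.6	TRUE	1	0	0	Probably	NotTolerated	High	Deleterious	Neutral	C65	0.40946
A12850G	ND5	Ile->Val	90.2	TRUE	1	0	0	Possibly	Tolerated	Neutral	Neutral	Neutral	C25	0.50297
A13535G	ND5	Asn->Ser	87.8	TRUE	1	0	0	Benign	NotTolerated	Low	Deleterious	Neutral	C45	NA
A13748G	ND5	Asn->Ser	85.4	TRUE	1	0	0	Benign	Tolerated	Neutral	Neutral	Neutral	C45	0.5082
C14310A	ND6	Gly->Trp	78.05	FALSE	1	0	0	Probably	NotTolerated	Medium	Deleterious	Disease	C65	0.71527
T14463C	ND6	Thr->Ala	90.2	TRUE	1	0	0	Benign	Tolerated	Neutral	Deleterious	Neutral	C55	0.15283
T15018A	Cytb	Phe->Tyr	100	FALSE	1	0	0	Possibly	NotTolerated	High	Deleterious	Disease	C15	0.68543
G15045A	Cytb	Arg->Gln	100	TRUE	1	0	0	Probably	NotTolerated	High	Deleterious	Disease	C35	0.59378
T15090C	Cytb	Ile->Thr	85.4	TRUE	1	0	1	Possibly	Tolerated	Low	Deleterious	Neutral	C65	0.42865
T15479C	Cytb	Phe->Leu	80.5	TRUE	1	0	0	Benign	Tolerated	Low	Deleterious	Neutral	C15	0.39962
C15483T	Cytb	Ser->Leu	80.5	TRUE	1	0	0	Possibly	Tolerated	Low	Deleterious	Neutral	C65	0.45816
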