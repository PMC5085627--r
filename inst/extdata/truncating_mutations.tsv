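label	gene	class	reported	zygosity
G4969A	ND2	nonsense	FALSE	homoplasmic
G5977A	COI	nonsense	FALSE	heteroplasmic
G7928A	COII	nonsense	FALSE	homoplasmic
G9253A	COIII	nonsense	FALSE	heteroplasmic
G10521A	ND4L	nonsense	FALSE	homoplasmic
T12794A	ND5	nonsense	FALSE	heteroplasmic
G13825A	ND5	nonsense	FALSE	homoplasmic
4520-4521delAC	ND2	frameshift	FALSE	homoplasmic
10952insC	ND4	frameshift	TRUE	homoplasmic
11032-11038:A7-6	ND4	frameshift	TRUE	mixed
11646insT	ND4	frameshift	FALSE	homoplasmic
11673-11677:C5-4	ND4	frameshift	FALSE	heteroplasmic
11673-11677:C5-6	ND4	frameshift	FALSE	homoplasmic
12418-12425:A8-7	ND5	frameshift	TRUE	heteroplasmic
12858insT	ND5	frameshift	FALSE	heteroplasmic
13128-13132:C5-4	ND5	frameshift	FALSE	homoplasmic
13170delA	ND5	frameshift	FALSE	homoplasmic
14495-14502:AAAT2-1	ND6	frameshift	FALSE	homoplasmic
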