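node	parent	defining_variants
mt-MRCA		
M	mt-MRCA	A16051G,C16071T
N	mt-MRCA	T16093C,C16104T
C	M	A16111T,G16129A
D	M	C16145T,A16154G
D4	D	T249C
G	M	C16172T,A16209G
Z	M	C16223T,A16234G
A	N	C16243T,A16249G
A4	A	C16278T,A16290G
B4	N	C16304T,A16311G
B4a	B4	C16320T,A73G
B4g	B4	T93C,C103T
F	N	C143T,A152G
R	N	T195C,A204G
Y	N	C235T,A247G
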