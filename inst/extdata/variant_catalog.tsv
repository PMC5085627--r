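label	status
G3392A	reported
T3644C	reported
T3679C	reported
G3745A	reported
C6340T	reported
T6681C	reported
G8989A	reported
T9187C	reported
A9355G	reported
G10573A	reported
A12850G	reported
A13535G	reported
A13748G	reported
T14463C	reported
G15045A	reported
T15090C	reported
T15479C	reported
C15483T	reported
10952insC	reported
11032-11038:A7-6	reported
12418-12425:A8-7	reported
A3243G	reported
G3244A	reported
A5514G	reported
T5628C	reported
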