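sample_id,tissue,target,ct1,ct2,ct3
case01.tumor,tumor,mt,15.81,15.92,15.88
case01.tumor,tumor,nuclear,23.95,24.05,23.99
case01.normal,normal,mt,17.42,17.36,17.45
case01.normal,normal,nuclear,23.61,23.72,23.66
case02.tumor,tumor,mt,16.55,16.49,16.6
case02.tumor,tumor,nuclear,24.12,24.03,24.08
case02.normal,normal,mt,16.95,17.02,16.99
case02.normal,normal,nuclear,23.88,23.95,23.91
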