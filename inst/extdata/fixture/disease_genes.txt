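# synthetic disease gene list (planted)
NM_000040
NM_000002
NM_000025
NM_000120
NM_000027
NM_000065
NM_000053
NM_000099
NM_000063
NM_000075
NM_000050
NM_000100
NM_000082
NM_000064
NM_000087
NM_000059
NM_000078
NM_000060
NM_000097
NM_000116
NM_000001
NM_000023
NM_000044
NM_000074
NM_000046
NM_000069
NM_000106
NM_000004
NM_000003
NM_000045
NM_000112
NM_000006
NM_000047
NM_000049
NM_000005
NM_000108
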