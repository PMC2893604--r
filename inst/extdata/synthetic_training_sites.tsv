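synth0001	25,42,61,67,96
synth0002	14,56,62
synth0003	16,22,43,84
synth0005	13,46,116
synth0006	6,27,40,108
synth0007	134
synth0008	67
synth0009	70,90
synth0010	80
synth0013	6,23,62
synth0014	63,112
synth0015	20
synth0016	153
synth0017	26,77,100
synth0018	104
synth0019	84
synth0020	70
synth0021	15,69
synth0022	17,35
synth0023	84
synth0024	9,22,50,71
synth0026	52
synth0027	38,58
synth0028	59,107
synth0029	14,62,81,129
synth0030	31,47
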