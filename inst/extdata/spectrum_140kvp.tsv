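# 140 kVp tungsten-anode x-ray spectrum, 12 bins (bin centers, keV).
# Lightly filtered diagnostic spectrum shape; weights are relative photon
# fluence per bin and are renormalized to sum to 1 on load.
energy_kev	weight
25	0.050
35	0.100
45	0.130
55	0.145
65	0.145
75	0.130
85	0.110
95	0.090
105	0.070
115	0.050
125	0.030
135	0.010
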