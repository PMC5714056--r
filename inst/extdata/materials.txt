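# ctmar material definitions
#
# One block per material:
#   material:    name (letters, digits, underscore)
#   density:     mass density in g/cm3
#   composition: whitespace-separated Element=massFraction pairs; fractions
#                must sum to 1 within 1e-6.
#
# Tissue-surrogate compositions follow common phantom-insert formulations;
# Cerrobend is the standard Bi/Pb/Sn/Cd low-melting-point alloy.

material: water
density: 1.000
composition: H=0.1119 O=0.8881

material: air
density: 0.001205
composition: N=0.755 O=0.232 Ar=0.013

material: solid_water
density: 1.004
composition: H=0.0950 C=0.6581 N=0.0240 O=0.1984 Cl=0.0014 Ca=0.0231

material: lung
density: 0.300
composition: H=0.0846 C=0.5938 N=0.0200 O=0.2732 Mg=0.0112 Si=0.0058 Cl=0.0114

material: adipose
density: 0.920
composition: H=0.1140 C=0.5980 N=0.0070 O=0.2810

material: breast
density: 0.990
composition: H=0.1060 C=0.3320 N=0.0300 O=0.5320

material: brain
density: 1.045
composition: H=0.1070 C=0.1450 N=0.0220 O=0.7120 P=0.0040 Cl=0.0100

material: liver
density: 1.090
composition: H=0.1020 C=0.1390 N=0.0300 O=0.7160 P=0.0030 Cl=0.0100

material: inner_bone
density: 1.140
composition: H=0.0850 C=0.4040 N=0.0580 O=0.3670 P=0.0320 Ca=0.0540

material: cortical_bone
density: 1.820
composition: H=0.0341 C=0.3141 N=0.0184 O=0.3650 Cl=0.0004 Ca=0.2680

material: titanium
density: 4.540
composition: Ti=1.0

material: cerrobend
density: 9.760
composition: Bi=0.500 Pb=0.267 Sn=0.133 Cd=0.100
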