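9
three-water chain, O-O 3.0 A
O        0.0000000000       0.0000000000       0.0000000000
H        0.7569503273       0.5858822766       0.0000000000
H       -0.7569503273       0.5858822766       0.0000000000
O        3.0000000000       0.0000000000       0.0000000000
H        3.7569503273       0.5858822766       0.0000000000
H        2.2430496727       0.5858822766       0.0000000000
O        6.0000000000       0.0000000000       0.0000000000
H        6.7569503273       0.5858822766       0.0000000000
H        5.2430496727       0.5858822766       0.0000000000
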