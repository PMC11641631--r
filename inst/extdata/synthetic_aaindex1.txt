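H SYNH000101
D Synthetic hydrophobicity-like scale (linear in O and C counts, sd 0.10)
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
     -0.021  0.666  -0.367  -1.170  -0.179  -0.158  -0.723  -0.294  -0.280  0.719
     0.769  0.722  0.490  0.051  0.385  -0.585  -0.379  -0.044  -0.583  0.413
//
H SYNP000102
D Synthetic polarity-like scale (linear in N and S counts, sd 0.15)
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
     0.430  2.934  1.350  0.473  0.078  1.185  0.484  0.310  0.647  0.670
     0.579  1.577  -0.016  0.584  0.850  0.561  0.896  0.516  0.744  0.817
//
H SYNR000103
D Synthetic ring-preference scale (linear in aromatic C, noiseless)
I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V
     0.100  0.100  0.100  0.100  0.100  0.100  0.100  0.100  1.150  0.100
     0.100  0.100  0.100  2.200  0.100  0.100  0.100  2.900  2.200  0.100
//
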