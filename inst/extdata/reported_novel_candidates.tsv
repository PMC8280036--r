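gene	fdr
SMAD6	4.83e-04
SPG7	8.89e-04
MSL2	9.62e-04
CYP27C1	1.39e-03
ITSN1	1.89e-03
PSD3	2.11e-03
POLR3A	2.99e-03
UBR3	5.41e-03
GALNT18	7.34e-03
DCX	7.43e-03
LRRC4	2.56e-02
SPAG9	3.15e-02
ST3GAL6	3.23e-02
YTHDC1	8.48e-02
RRAGC	9.00e-02
DNAH17	9.58e-02
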