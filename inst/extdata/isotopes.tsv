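element	isotope_mass	abundance
H	1.00782503207	0.999885
H	2.01410177785	0.000115
D	2.01410177785	1.0
C	12.0	0.9893
C	13.00335483780	0.0107
N	14.00307400480	0.99636
N	15.00010889820	0.00364
O	15.99491461956	0.99757
O	16.99913170000	0.00038
O	17.99916100000	0.00205
P	30.97376163000	1.0
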