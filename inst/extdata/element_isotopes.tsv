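element	isotope_mass	abundance
C	12.0	0.9893
C	13.0033548378	0.0107
H	1.0078250319	0.999885
H	2.0141017779	0.000115
N	14.0030740052	0.99632
N	15.0001088984	0.00368
O	15.9949146221	0.99757
O	16.9991315	0.00038
O	17.9991604	0.00205
S	31.97207069	0.9493
S	32.9714585	0.0076
S	33.96786683	0.0429
S	35.96708088	0.0002
P	30.97376151	1.0
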