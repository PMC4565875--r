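# Stable-isotope masses (Da) and abundances for C, H, N, O, P, S.
# Masses: AME/CODATA atomic masses. Abundances: IUPAC 2005 representative
# isotopic composition (the vintage used by the classic ultrahigh-resolution
# isotope-pattern tools). Columns are tab-separated; nucleons is the mass
# number of the isotope.
element	isotope	nucleons	mass_Da	abundance
C	12C	12	12.000000000	0.9893
C	13C	13	13.003354835	0.0107
H	1H	1	1.007825032	0.999885
H	2H	2	2.014101778	0.000115
N	14N	14	14.003074005	0.99632
N	15N	15	15.000108898	0.00368
O	16O	16	15.994914620	0.99757
O	17O	17	16.999131757	0.00038
O	18O	18	17.999159613	0.00205
P	31P	31	30.973761998	1.0
S	32S	32	31.972071174	0.9493
S	33S	33	32.971458910	0.0076
S	34S	34	33.967867004	0.0429
S	36S	36	35.967080710	0.0002
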