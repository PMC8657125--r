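gene	Basal	Her2	LumA	LumB	Normal
ANLN	1.0189	0.5795	-0.6271	0.8761	-1.4107
CEP55	1.1177	0.4598	-0.7168	0.3566	-1.2273
ORC6L	0.8599	0.6459	-0.7504	0.8214	-1.3942
CCNE1	1.1337	0.4806	-0.9685	0.7796	-1.4462
EXO1	1.2127	0.525	-1.1995	0.9077	-1.5278
PTTG1	1.0628	0.5499	-0.5761	0.6184	-1.3889
CDC20	1.056	0.6505	-0.7237	0.6006	-1.335
KIF2C	1.0317	0.3678	-0.7031	0.9275	-1.4672
RRM2	1.0388	0.3324	-0.8488	0.396	-1.2826
CDC6	1.1518	0.4547	-0.8923	0.5998	-1.4531
KNTC2	1.0657	0.2818	-1.1482	0.892	-1.2033
TYMS	0.989	0.387	-0.9136	0.7679	-1.4155
CDCA1	1.027	0.5499	-0.8627	0.768	-1.5019
MELK	1.0935	0.3117	-0.7466	0.7734	-1.1481
UBE2C	1.245	0.5434	-0.8639	0.8211	-1.4112
CENPF	1.2149	0.465	-0.7618	0.8341	-1.6532
MKI67	1.072	0.2923	-0.7847	0.7217	-1.7325
UBE2T	0.9975	0.5752	-0.8048	0.7893	-1.4539
BIRC5	0.8765	0.1973	-0.7347	0.795	-1.28
CCNB1	0.8809	0.4901	-1.1703	0.6512	-1.3268
MYBL2	0.8766	0.4482	-0.8222	0.409	-1.1136
NAT1	-1.0705	-0.7977	0.9422	0.6865	0.1479
MAPT	-1.0686	-0.7435	0.8516	0.5341	0.4294
SLC39A6	-1	-0.5884	1.0306	0.6025	0.4561
BCL2	-1.2021	-0.6239	0.9317	0.2434	0.1769
BLVRA	-1.3605	-0.5423	0.6078	0.5148	0.109
CXXC5	-1.3376	-0.6568	1.0684	0.6015	0.1136
GPR160	-1.4735	-0.9005	0.8339	0.579	0.3539
MLPH	-1.4454	-0.6086	0.7539	0.5532	0.4452
BAG1	-1.1363	-0.7155	0.9591	0.5605	0.2039
MDM2	-1.2368	-0.7379	1.0366	0.8127	0.3726
TMEM45B	-1.1538	-0.7481	0.9269	0.5271	0.0077
ESR1	-1.6466	-0.8685	1.36	0.8022	0.3349
PGR	-1.1166	-1.1824	0.691	0.283	0.4924
FOXA1	-1.4638	0.3589	1.056	0.9862	0.1547
ERBB2	-0.5104	1.784	-0.3864	0.0407	-0.0336
GRB7	-0.518	1.9266	-0.4485	0.2251	-0.4475
FGFR4	-0.0951	1.0343	-0.4006	0.0337	-0.1135
MIA	1.7017	-0.4051	-0.9809	-0.8142	0.3752
FOXC1	1.4606	0.0743	-1.0557	-0.8184	0.3231
CDH3	1.6564	0.037	-1.0866	-0.7602	0.3638
EGFR	1.5242	-0.117	-0.9225	-0.6961	0.2848
PHGDH	1.6069	-0.0509	-0.7579	-0.9009	0.1858
ACTR3B	1.2066	0.0155	-0.9479	-0.7597	0.4822
MYC	1.2042	-0.0859	-1.1916	-0.8355	0.2366
KRT5	1.4871	-0.5734	-0.8281	-1.4939	1.149
KRT14	1.1683	-0.4684	-0.8537	-1.3572	0.7217
KRT17	1.4434	-0.4727	-0.8231	-0.8148	1.0623
SFRP1	1.599	-0.4472	-0.7964	-1.059	0.7948
MMP11	-0.1352	0.6214	0.1133	0.8969	-1.392
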