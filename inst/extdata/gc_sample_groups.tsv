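Tumor type	Sample	Group description	KRT18 expression (CPM)
Diffuse	GSM3101199	KRT18_low	4.257
Diffuse	GSM3101104	KRT18_low	5.874
Diffuse	GSM3101115	KRT18_low	6.27
Diffuse	GSM3101196	KRT18_low	7.387
Diffuse	GSM3101081	KRT18_low	7.457
Diffuse	GSM3101192	KRT18_low	7.465
Diffuse	GSM3101177	KRT18_low	7.538
Diffuse	GSM3101153	KRT18_low	7.558
Diffuse	GSM3101158	KRT18_low	7.788
Diffuse	GSM3101137	KRT18_low	7.879
Diffuse	GSM3101145	KRT18_low	7.926
Diffuse	GSM3101194	KRT18_low	7.939
Diffuse	GSM3101111	KRT18_low	7.966
INT	GSM3101065	KRT18_low	8.014
Diffuse	GSM3101093	KRT18_low	8.048
Diffuse	GSM3101178	KRT18_low	8.053
Diffuse	GSM3101092	KRT18_low	8.07
Diffuse	GSM3101200	KRT18_low	8.12
Diffuse	GSM3101186	KRT18_low	8.132
Diffuse	GSM3101139	KRT18_low	8.164
INT	GSM3101069	KRT18_low	8.175
Diffuse	GSM3101067	KRT18_low	8.289
Diffuse	GSM3101148	KRT18_low	8.335
Diffuse	GSM3101195	KRT18_low	8.35
Diffuse	GSM3101112	KRT18_low	8.362
INT	GSM3101107	KRT18_high	11.292
INT	GSM3101130	KRT18_high	11.053
Diffuse	GSM3101180	KRT18_high	11.046
INT	GSM3101122	KRT18_high	11.042
Diffuse	GSM3101127	KRT18_high	10.857
Diffuse	GSM3101185	KRT18_high	10.752
Diffuse	GSM3101198	KRT18_high	10.751
Diffuse	GSM3101087	KRT18_high	10.694
INT	GSM3101083	KRT18_high	10.66
Diffuse	GSM3101075	KRT18_high	10.629
Diffuse	GSM3101100	KRT18_high	10.564
Diffuse	GSM3101156	KRT18_high	10.533
Diffuse	GSM3101099	KRT18_high	10.436
Diffuse	GSM3101108	KRT18_high	10.42
Diffuse	GSM3101109	KRT18_high	10.392
Diffuse	GSM3101064	KRT18_high	10.368
Diffuse	GSM3101098	KRT18_high	10.351
Diffuse	GSM3101146	KRT18_high	10.296
Diffuse	GSM3101181	KRT18_high	10.249
Diffuse	GSM3101172	KRT18_high	10.231
Diffuse	GSM3101183	KRT18_high	10.207
Diffuse	GSM3101188	KRT18_high	10.196
INT	GSM3101138	KRT18_high	10.173
Diffuse	GSM3101136	KRT18_high	10.17
Diffuse	GSM3101169	KRT18_high	10.146
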