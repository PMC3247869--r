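short_name	n_genes	n_known_function	n_sm_enzyme	n_pairs_sm	pct_positive	weight
ECK12	4496	3185	1000	495510	0.621	1.000
EC157	5475	1032	706	248865	1.327	0.884
ECCFT	5379	721	577	166176	0.968	0.856
SHIG	4207	886	597	177310	1.020	0.795
VCHO	3949	863	583	169653	1.244	0.528
CAULO	3818	919	615	188805	0.964	0.362
MTBC	4235	760	569	161596	1.157	0.238
MTBR	3968	811	578	166753	1.409	0.238
FRANT	1671	491	317	50086	1.512	0.230
HPY	1609	415	228	25878	1.946	0.155
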