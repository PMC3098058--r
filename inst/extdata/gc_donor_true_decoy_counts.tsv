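oligo	true_count	decoy_count	posterior	normalized
CAGGCAAGT	3263	36400	0.082	0.914
AAGGCAAGT	3246	41193	0.073	0.744
GAGGCAAGT	1898	35375	0.051	0.609
ACGGCAAGT	143	4519	0.031	0.555
AAGGCGAGT	199	6570	0.029	0.546
CAGGCGAGT	231	8750	0.026	0.535
ATGGCAAGT	580	30928	0.018	0.514
TCGGCAAGT	64	3971	0.016	0.497
GAGGCGAGT	141	9746	0.014	0.491
CCGGCAAGT	62	4534	0.013	0.486
AAGGCAAGC	415	36154	0.011	0.474
TAGGCAAGT	398	34927	0.011	0.452
CGGGCAAGT	64	5963	0.011	0.440
AAGGCACGT	92	10006	0.009	0.436
CTGGCAAGT	304	34884	0.009	0.426
AAGGCAAGG	475	54694	0.009	0.405
AAGGCAAGA	517	61104	0.008	0.379
CAGGCAAGA	365	55964	0.006	0.356
CAGGCAAGG	351	55387	0.006	0.337
CAGGCAAGC	275	44919	0.006	0.321
GAGGCACGT	51	9371	0.005	0.312
AGGGCAAGT	175	32213	0.005	0.306
TTGGCAAGT	188	36674	0.005	0.297
AACGCAAGT	19	3870	0.005	0.291
GCGGCAAGT	20	4303	0.005	0.290
GAGGCAAGC	166	37252	0.004	0.285
CGCGCAAGC	5	1155	0.004	0.281
AAGGCAGGT	292	75658	0.004	0.273
CCGGCACGT	9	2455	0.004	0.265
CAGGCACGT	122	35158	0.003	0.262
CCGGCGAGT	7	2036	0.003	0.258
GAGGCATGT	114	33194	0.003	0.255
TCGGCGAGT	4	1184	0.003	0.252
CAGGCAGGT	271	81896	0.003	0.245
TAGGCGAGT	12	3855	0.003	0.238
ATGGCGAGT	18	5790	0.003	0.237
AAAGCAAGT	209	67530	0.003	0.231
ACGGCACGT	5	1617	0.003	0.225
AAGGCATGT	174	60195	0.003	0.220
AAGGCGCGT	5	1733	0.003	0.216
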