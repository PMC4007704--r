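genome_id	genome_length_bp	n_genes	n_trna	n_is_elements	pct_hypothetical	pct_assigned
UCC2003	2422684	1854	54	49	27	73
S27	2294458	1748	51	25	27	73
689b	2331707	1821	52	32	28	72
NCFB_2258	2315904	1834	52	36	26	74
JCM_7017	2288919	1770	52	38	24	76
JCM_7019	2359009	1915	55	54	27	73
12L	2244624	1765	52	40	27	73
ACS-071-V-Sch8b	2327492	1826	53	12	20	80
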