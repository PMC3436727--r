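# Published per-linkage-group marker counts for the Eucalyptus composite
# reference linkage map (11 linkage groups). Columns: linkage group,
# map length (cM), DArT / SSR / gene marker positions, total positions,
# average marker interval (cM), multicopy DArT positions.
linkage_group	length_cM	dart	ssr	gene	total	mean_interval_cM	multicopy_dart
1	93.8	250	12	0	262	0.42	5
2	102.1	451	29	0	480	0.24	18
3	105.6	429	18	2	449	0.28	21
4	80.9	219	9	3	231	0.41	12
5	95.9	366	8	0	374	0.30	24
6	125.3	408	43	1	452	0.31	15
7	87.7	305	9	1	315	0.33	18
8	137.3	540	26	0	566	0.28	19
9	82.9	312	20	0	332	0.29	10
10	97.8	336	20	1	357	0.30	12
11	97.3	354	19	0	373	0.31	17
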