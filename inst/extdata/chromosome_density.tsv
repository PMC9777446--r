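chrom	effective_length_bp	n_variants	per_mb	p_value
1	231223641	64	0.276788306	0.309486126
2	240863511	71	0.294772752	0.39856174
3	198255541	67	0.337947679	0.625386241
4	189962376	58	0.305323618	0.453773416
5	181358067	55	0.303267458	0.442908357
6	170078524	60	0.352778226	0.697688611
7	158970135	60	0.377429383	0.801517446
8	144768136	54	0.37301026	0.78465846
9	122084564	41	0.335832792	0.614630158
10	133263006	45	0.33767811	0.624020457
11	134634058	37	0.274819021	0.300273823
12	133137821	34	0.255374466	0.216709904
13	97983128	29	0.295969322	0.404743508
14	91660769	31	0.338203578	0.626681306
15	85089576	26	0.305560343	0.455026684
16	83378703	32	0.38379105	0.824340228
17	83481871	24	0.287487567	0.36152445
18	80089650	24	0.299664189	0.4239761
19	58440758	8	0.136890764	0.008989368
20	63944268	15	0.234579275	0.144314325
21	40088623	9	0.224502598	0.115899249
22	40181019	14	0.348423219	0.677094783
X	154893034	84	0.542309734	0.998853971
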