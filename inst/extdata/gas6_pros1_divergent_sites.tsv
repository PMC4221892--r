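aln_col	gas6_pos1	gas6_pos2	gas6_aa	pros1_pos	pros1_aa	methods
	37	37	E	31	Q	B_Ib
	384	341	Q	345	D	B_Ia
	51	51	Q	44	S	PS
	405	362	N	366	E	B_Ia,B_Ib
	60	60	H	53	N	B_II
	415	372	P	376	D	B_II,PS
	97	97	N	90	R	B_Ia,B_Ib
	423	380	Q	384	N	B_Ib
	98	98	K	91	S	B_Ia,B_II
	432	389	R	393	H	FD,B_Ib
	100	100	G	93	Q	B_II
	435	392	V	396	S	FD,B_II,PS
	102	102	P	103	S	B_Ia
	445	402	K	406	D	B_Ib
	105	105	K	106	A	B_Ib,B_II
	448	405	V	409	K	FD,B_Ib
	106	106	N	107	Y	B_Ib
	455	412	P	416	P	B_Ia
	110	110	A	111	R	FD,B_Ia,B_II
	456	413	E	417	E	B_Ib
	114	114	Q	115	N	B_Ia
	457	414	R	418	N	B_Ia
	123	123	N	124	L	B_Ia,B_Ib
	463	420	N	424	K	B_II
	134	134	Q	135	K	B_Ib
	465	422	T	426	Y	FD
	136	136	L	137	G	FD
	471	428	F	432	R	FD,B_Ia,B_Ib,B_II
	141	141	F	142	T	FD
	473	430	E	434	V	B_II
	143	143	L	144	T	B_Ia
	496	453	G	458	Q	FD,B_II
	146	146	A	147	P	B_Ia
	497	454	E	459	G	B_II
	161	161	S	162	K	B_Ib
	498	455	D	460	A	B_II
	162	162	Q	163	D	FD
	508	465	N	470	K	B_II
	170	170	I	174	I	B_Ib
	510	467	R	472	N	B_Ia,B_Ib,B_II
	189	189	S	193	L	B_Ia
	512	469	Q	474	H	B_Ib,B_II
	192	192	G	196	K	B_Ia
	517	474	T	479	V	FD
	203	203	D	207	L	B_II
	518	475	E	480	E	FD,B_Ia
	204	204	S	209	P	B_Ib
	526	483	S	488	S	B_Ia
	218	218	S	223	D	B_Ib
	585	542	Y	542	S	B_Ib,B_II
	222	222	L	227	E	B_II
	586	543	H	543	T	FD,B_Ia,B_Ib
	224	224	D	229	P	B_Ia,B_Ib
	588	545	T	545	E	B_Ia,B_Ib
	248	248	E	253	A	B_II
	593	550	K	547	S	B_Ib
	266	266	G	271	K	B_Ia,B_Ib,B_II
	595	552	L	549	D	B_Ia,B_Ib,B_II
	274	274	M	279	Q	FD
	614	571	D	569	S	B_Ib
	322	279	D	284	V	B_Ib
	618	575	H	573	S	FD,B_Ib
	332	289	A	294	D	B_Ia,B_Ib
	623	580	S	578	R	FD,B_Ib
	337	294	S	299	L	B_II
	626	583	D	581	R	B_Ia
	343	300	M	305	Q	PS
	639	596	Q	594	T	FD
	351	308	R	312	Y	B_II,PS
	640	597	S	595	I	B_Ib
	356	313	R	317	L	B_II
	641	598	E	596	S	FD,B_Ib
	357	314	L	318	P	B_Ia,B_Ib,PS
	657	614	H	610	A	B_Ia,B_II,PS
	381	338	G	342	E	B_II
	703	660	Y	656	S	FD,B_Ia,B_Ib
	383	340	H	344	I	FD,B_Ia,B_Ib
	717	674	E	670	W	B_Ib
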