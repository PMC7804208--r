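table	panel	instance	true_status	main_posterior	remedy_posterior	conclusion
doubt_band	A	118	case	0.5132	0.6442	improved
doubt_band	A	811	case	0.5005	0.9954	improved
doubt_band	A	1024	case	0.5225	0.9034	improved
doubt_band	A	1077	control	0.4590	0.2712	improved
doubt_band	A	1126	case	0.5140	0.9823	improved
doubt_band	A	1128	control	0.4987	0.0508	improved
doubt_band	A	1365	control	0.4525	0.3326	improved
doubt_band	A	1482	case	0.5277	0.6845	improved
doubt_band	A	1655	control	0.4545	0.0392	improved
doubt_band	B	29	case	0.4896	0.6215	corrected
doubt_band	B	39	case	0.5495	0.9332	improved
doubt_band	B	375	case	0.5290	0.9450	improved
doubt_band	B	435	control	0.4726	0.0838	improved
doubt_band	B	1026	case	0.5352	0.8606	improved
doubt_band	B	1086	control	0.4549	0.1960	improved
doubt_band	B	1495	case	0.5015	0.7915	improved
doubt_band	B	1597	case	0.5398	0.8696	improved
errors	B	29	case	0.4896	0.6215	corrected
errors	C	318	control	0.5171	0.1060	corrected
errors	D	414	control	0.5379	0.1386	corrected
errors	C	1291	case	0.4465	0.6449	corrected
errors	E	1444	case	0.4680	0.8689	corrected
errors	F	1356	control	0.5486	0.0765	corrected
errors	E	1724	control	0.6190	0.0276	corrected
errors	F	1982	case	0.4549	0.7723	corrected
errors	E	2153	case	0.4633	0.9114	corrected
errors	G	1354	case	0.3288	0.5652	corrected
errors	H	581	case	0.4947	0.8736	corrected
errors	I	1114	case	0.4706	0.9645	corrected
errors	J	109	control	0.5658	0.1494	corrected
errors	K	1006	control	0.5111	0.1906	corrected
errors	L	1107	case	0.4596	0.7027	corrected
errors	K	1079	case	0.3978	0.9797	corrected
errors	L	2141	case	0.4224	0.9866	corrected
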