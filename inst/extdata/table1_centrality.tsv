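province	in_degree	out_degree	degree	betweenness	closeness
Beijing	11	4	36.667	0.807	57.692
Tianjin	8	3	26.667	0.23	53.571
Hebei	14	5	46.667	1.943	61.224
Shanxi	7	7	33.333	0.69	60
Inner Mongolia	0	7	23.333	0.272	56.604
Liaoning	2	8	30	0.706	58.824
Jilin	2	8	26.667	0.272	57.692
Heilongjiang	1	9	30	0.706	58.824
Shanghai	4	3	13.333	0	50.847
Jiangsu	27	6	90	17.409	90.909
Zhejiang	12	3	40	1.825	62.5
Anhui	12	7	40	0.915	62.5
Fujian	3	10	33.333	0.497	60
Jiangxi	5	9	30	0.042	58.824
Shandong	25	7	83.333	11.24	85.714
Henan	25	8	83.333	9.588	85.714
Hubei	18	8	66.667	3.077	75
Hunan	13	9	60	2.837	71.429
Guangdong	14	11	63.333	3.391	73.171
Guangxi	4	7	26.667	0.23	54.545
Hainan	0	4	13.333	0	50.847
Chongqing	9	9	50	0.847	66.667
Sichuan	9	10	50	0.707	66.667
Guizhou	6	9	33.333	0.114	58.824
Yunnan	4	10	36.667	0.225	61.224
Tibet	0	13	43.333	0.496	63.83
Shaanxi	9	10	50	1.17	66.667
Gansu	4	11	46.667	0.805	65.217
Qinghai	0	11	36.667	0.246	61.224
Ningxia	1	10	33.333	0.46	60
Xinjiang	1	14	50	1.699	66.667
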