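site_id,location,sampling_year,chemical,conc_min,conc_max,conc_mean,source
1,Luoma Lake,2015,BPA,49,110,86,ref50
1,Luoma Lake,2015,BPS,0,94,21,ref50
1,Luoma Lake,2015,BPF,3.5,14,6.8,ref50
2,Luoma Lake,2020,BPA,120,280,200,ref51
2,Luoma Lake,2020,BPS,3.2,7.7,5.45,ref51
2,Luoma Lake,2020,BPF,87.4,230,159,ref51
3,Taihu Lake,2013,BPA,4.2,14,8.5,ref52
3,Taihu Lake,2013,BPS,0.28,67,6,ref52
3,Taihu Lake,2013,BPF,0,5.6,0.83,ref52
4,Taihu Lake,2015,BPA,27,565,86,ref53
4,Taihu Lake,2015,BPS,4.5,1569,101,ref53
4,Taihu Lake,2015,BPF,0,1634,114,ref53
5,Taihu Lake,2016,BPA,28,560,97,ref50
5,Taihu Lake,2016,BPS,4.5,1600,120,ref50
5,Taihu Lake,2016,BPF,0,1600,140,ref50
6,Taihu Lake,2016,BPA,19,68,26,ref54
6,Taihu Lake,2016,BPS,4.1,160,16,ref54
6,Taihu Lake,2016,BPF,26,720,78,ref54
7,"Taihu Lake, Gehu Lake and Rivers",2018,BPA,47.8,633,196,ref55
7,"Taihu Lake, Gehu Lake and Rivers",2018,BPS,6.56,293,56.1,ref55
7,"Taihu Lake, Gehu Lake and Rivers",2018,BPF,0.48,36.7,5.82,ref55
8,Bulao River,2020,BPA,220,310,265,ref51
8,Bulao River,2020,BPS,5.5,7.8,6.65,ref51
8,Bulao River,2020,BPF,130,220,175,ref51
9,Dongjiang River,2015,BPA,23.7,2180,406,ref2
9,Dongjiang River,2015,BPS,0.07,133,12.7,ref2
9,Dongjiang River,2015,BPF,0.98,255,25.2,ref2
10,Fangting River,2020,BPA,250,290,270,ref51
10,Fangting River,2020,BPS,3.6,6.1,4.85,ref51
10,Fangting River,2020,BPF,200,220,210,ref51
11,Guangzhou Section of Pearl River,2022,BPA,60.5,187.5,124,ref56
11,Guangzhou Section of Pearl River,2022,BPS,1.7,102.1,51.9,ref56
11,Guangzhou Section of Pearl River,2022,BPF,5.4,118.8,62.1,ref56
12,Hunhe river,2013,BPA,4.4,107,40,ref52
12,Hunhe river,2013,BPS,0.61,46,11,ref52
12,Hunhe river,2013,BPF,ND,ND,ND,ref52
13,Irrigation Rivers in Zhangjiagang City,2023,BPA,4.66,64.77,22.19,ref57
13,Irrigation Rivers in Zhangjiagang City,2023,BPS,0,74.04,6.42,ref57
13,Irrigation Rivers in Zhangjiagang City,2023,BPF,0,22.88,1.04,ref57
14,Lanzhou Section of Yellow River,2017,BPA,7.8,138.5,42.6,ref58
14,Lanzhou Section of Yellow River,2017,BPS,0,19.4,5.6,ref58
14,Lanzhou Section of Yellow River,2017,BPF,/,/,/,ref58
15,Laoyi River,2020,BPA,210,220,215,ref51
15,Laoyi River,2020,BPS,4.2,4.7,4.45,ref51
15,Laoyi River,2020,BPF,91.9,130,111,ref51
16,Liaohe river,2013,BPA,5.9,141,47,ref52
16,Liaohe river,2013,BPS,0.22,52,14,ref52
16,Liaohe river,2013,BPF,ND,ND,ND,ref52
17,Liuxi River,2016,BPA,75.6,7480,922,ref59
17,Liuxi River,2016,BPS,19.9,65600,3720,ref59
17,Liuxi River,2016,BPF,0,474,82.8,ref59
18,Luoma Lake Inflow Rivers,2020,BPA,120,310,215,ref60
18,Luoma Lake Inflow Rivers,2020,BPS,3.6,7.8,5.7,ref60
18,Luoma Lake Inflow Rivers,2020,BPF,91.9,230,161,ref60
19,Pearl River,2015,BPA,0,98,73,ref49
19,Pearl River,2015,BPS,0,135,135,ref49
19,Pearl River,2015,BPF,448,1110,773,ref49
20,"River, Port, Lake and Chanel of Jiangyan District",2018,BPA,19,702,371.5,ref61
20,"River, Port, Lake and Chanel of Jiangyan District",2018,BPS,3.4,83.5,37.1,ref61
20,"River, Port, Lake and Chanel of Jiangyan District",2018,BPF,0,270.6,42.9,ref61
21,"Rivers, Lakes and Reservoirs",2017,BPA,0,34.9,12.8,ref62
21,"Rivers, Lakes and Reservoirs",2017,BPS,0,5.2,1.1,ref62
21,"Rivers, Lakes and Reservoirs",2017,BPF,0,12.56,2.18,ref62
22,West River,2015,BPA,0,43,43,ref49
22,West River,2015,BPS,ND,ND,ND,ref49
22,West River,2015,BPF,0,105,64,ref49
23,Yangtze River and Urban River in Nanjing,2018,BPA,85.9,586.4,315.8,ref63
23,Yangtze River and Urban River in Nanjing,2018,BPS,12.9,143.4,51.6,ref63
23,Yangtze River and Urban River in Nanjing,2018,BPF,1.4,27.3,12.2,ref63
24,Yangtze River and Urban River in Nanjing,2018,BPA,120,554,253,ref64
24,Yangtze River and Urban River in Nanjing,2018,BPS,2.24,73.3,39.2,ref64
24,Yangtze River and Urban River in Nanjing,2018,BPF,0,4.76,2.2,ref64
25,Yi River,2020,BPA,120,170,145,ref51
25,Yi River,2020,BPS,4.1,6.4,5.25,ref51
25,Yi River,2020,BPF,110,220,165,ref51
26,Zhongyun River,2020,BPA,180,300,240,ref51
26,Zhongyun River,2020,BPS,4.2,6,5.1,ref51
26,Zhongyun River,2020,BPF,110,230,170,ref51
27,Zhujiang River,2015,BPA,118,1770,471,ref2
27,Zhujiang River,2015,BPS,16.6,103,44.5,ref2
27,Zhujiang River,2015,BPF,6.54,34.4,12.2,ref2
28,Pearl River Delta,2020,BPA,1.7,93,9.5,ref65
28,Pearl River Delta,2020,BPS,0.039,7,0.54,ref65
28,Pearl River Delta,2020,BPF,0,1.6,0.016,ref65
29,Pearl River Estuary,2017,BPA,9.48,173,24.6,ref66
29,Pearl River Estuary,2017,BPS,1.6,59.8,10.3,ref66
29,Pearl River Estuary,2017,BPF,2.37,282,35,ref66
30,Seawater of Beibu Gulf,2017,BPA,5.26,12.04,8.38,ref67
30,Seawater of Beibu Gulf,2017,BPS,0.07,0.63,0.34,ref67
30,Seawater of Beibu Gulf,2017,BPF,ND,ND,ND,ref67
31,Seawater of East China Sea,2019,BPA,2.7,52,23,ref68
31,Seawater of East China Sea,2019,BPS,0.15,12,2.2,ref68
31,Seawater of East China Sea,2019,BPF,ND,ND,ND,ref68
32,Seawater of Hangzhou bay,2012,BPA,6.59,74.58,26,ref69
32,Seawater of Hangzhou bay,2012,BPS,0.29,18.99,4.6,ref69
32,Seawater of Hangzhou bay,2012,BPF,0,3.47,3.2,ref69
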