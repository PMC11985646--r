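id,rt_min,polarity,precursor_mz,ms2,true_name,note
1,4.80,negative,609.1324,463;301;177;151,Hesperidin,
2,4.86,negative,461.0770,285;257;135,Kaempferol-O-hexuronide,
3,5.09,negative,477.0676,301;179;151,Quercetin-O-hexuronide,
4,5.33,negative,609.1437,447;285;151,Luteolin-di-O-hexoside,
5,5.38,negative,447.0947,357;327;285;151;135,Luteolin-C-hexoside,
6,5.52,negative,445.0770,269;117,Baicalein-O-hexuronide,
7,5.64,negative,625.1737,463;301;283,Quercetin-O-di-hexoside,
8,6.18,negative,463.0918,301;283;255;151,Isoquercitrin,
9,6.41,positive,433.1357,343;313;271,Apigenin-C-hexoside,
10,6.48,positive,611.1806,465;303,Rutin,
11,6.50,negative,449.1194,287;151;135,Eriodictyol-O-hexoside,
12,6.52,negative,463.0938,301;271;255;151,Hyperoside,
13,6.57,negative,431.0989,269,Apigenin-O-hexoside,
14,6.59,negative,447.0909,285,Maritimetin-O-hexoside,
15,6.59,negative,593.1467,285,Kaempferol-O-neohesperidoside,
16,6.62,negative,577.1507,431;285,Kaempferol-O-bis-deoxyhexoside,
17,6.66,negative,447.0921,285,Luteolin-O-hexoside,
18,6.66,negative,623.1590,315;300,Isorhamnetin-O-deoxyhexosyl-hexoside,
19,6.79,negative,451.1404,289;271;179;163;153,Okanin-O-hexoside,
20,6.91,negative,433.1115,271;151;119,Naringenin-O-hexoside,
21,7.10,negative,577.1575,431;269,Vitexin-O-deoxyhexoside,
22,7.16,negative,479.1038,317,Gossypin,
23,7.27,negative,507.1129,492;345,Syringetin-O-hexoside,
24,7.30,negative,463.1217,301;283;135,Quercetin-O-hexoside,
25,7.46,negative,419.1226,287;259;231,Kaempferol-O-pentoside,printed under the deprotonated column but fragments follow protonated arithmetic
26,7.46,negative,597.1898,435;303,Quercetin-O-hexosyl-pentoside,
27,7.54,negative,477.1333,315;300;151,Isorhamnetin-O-hexoside,
28,7.89,negative,435.1261,273;151;119,Phlorizin,
29,8.63,negative,433.1016,301;193;161;151,Quercetin-O-pentoside,
30,8.66,negative,287.0629,213;151;135;107,Eriodictyol,
31,8.83,negative,591.1729,283;268,Acacetin-O-rutinoside,
32,8.95,negative,593.1296,447;285,Kaempferol-O-(p-coumaroyl)-hexoside,
33,9.22,negative,301.0233,255;193;151;135;121,Quercetin,
34,10.13,negative,269.0447,159;151;133;117,Apigenin,
35,10.31,negative,301.0724,286;151;134,Hesperetin,
36,10.34,negative,285.0397,257;177;151;133;107,Luteolin,
37,10.56,negative,299.0556,284;256;151,Trihydroxy-methoxyflavone,
38,13.16,negative,283.0606,268;151;131,Acacetin,
39,13.43,negative,315.0881,300;269;151;107,Isorhamnetin,
40,14.35,negative,271.0979,225;136;122,Naringenin,
41,19.81,positive,317.1220,,Rhamnetin,
42,19.82,positive,301.1492,,Kaempferide,
43,1.24,negative,153.0193,109;91,Gentisic acid,
44,1.24,negative,179.0550,161;135,Caffeic acid,
45,1.73,negative,353.0866,191;179;161;135,Chlorogenic acid,
46,2.52,negative,167.0331,149;123;108,Homogenentisic acid,
47,2.77,negative,137.0242,93;75,Hydroxybenzoic acid,
48,3.37,negative,163.0233,119;101,Coumaric acid,
49,4.26,negative,153.0183,135;109;91,Protocatechuic acid,
50,4.82,negative,183.0079,139;109,Dihydroxymandelate,
51,5.24,negative,385.1803,223;205,Sinapic acid-O-hexoside,
52,6.50,negative,167.0341,152;123;108,Methoxysalicylic acid,
53,8.40,negative,193.0501,178;161;149;133,Ferulic acid,
54,1.27,negative,175.0423,157;131;113,Hydroxy-Methylcoumarin,
55,2.68,negative,339.0741,177;133,Esculin,
56,4.68,negative,177.0187,149;133;105,Dihydroxycoumarin,
57,7.09,negative,193.0547,178,Scopoletin,
58,1.01,negative,133.0145,115;89;71,Malic acid,
59,1.04,negative,115.0022,71,Maleic acid,
60,1.06,negative,103.0020,59,Hydroxy-butyric acid,
61,1.07,negative,89.0238,71,Lactic acid,
62,1.11,negative,117.0177,99;73,Succinic acid,
63,1.15,negative,191.0556,173;129;111;85,Citrate,
64,1.19,negative,149.0448,131;89;87,Tartrate,
65,1.25,negative,146.9487,129;85,Citramalate,
66,1.28,negative,175.0605,157;131;113;69,Isopropylmalic acid,
67,1.35,negative,145.0258,127;109;101,Methylglutaric acid,
68,2.27,negative,165.0562,147;121;103,Phenyllactic acid,
69,4.90,negative,191.0559,173;127;93,Quinic acid,
70,5.09,negative,173.0432,155;137;131;111;93,Shikimic acid,
71,1.11,negative,175.1210,,Arginine,
72,1.55,negative,130.0488,,Oxoproline,
73,1.71,negative,130.0862,,Hydroxyproline,
74,2.15,negative,166.0876,,Phenylalanine,
75,2.80,negative,203.0821,,Tryptophan,
76,3.94,negative,144.0459,,Homoisoleucine,
77,12.82,negative,271.2264,253;212,Hydroxy-hexadecanoic acid,
78,18.48,negative,277.2177,233,Linolenic acid,
79,1.36,negative,181.0724,,Mannitol,
80,2.23,negative,343.1402,,Maltitol,
81,2.46,negative,503.1371,341;179,Maltotriose,
82,3.82,negative,341.0872,,Melibiose,
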