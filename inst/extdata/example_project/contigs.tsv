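Contig_ID	Length_bp	Tax	Bin_ID	Reads_S1	Bases_S1	Coverage_S1	Reads_S2	Bases_S2	Coverage_S2
G01_C001	7576	k_Bacteria;p_Phylum1;c_Class1;o_Order1;f_Family1;g_Genus1;s_Genus1 species1	bin_G01	11762	1764300	232.8801478353	8222	1233300	162.7903907075
G01_C002	8947	k_Bacteria;p_Phylum1;c_Class1;o_Order1;f_Family1;g_Genus1;s_Genus1 species1	bin_G01	13883	2082450	232.7539957528	9745	1461750	163.3787861853
G01_C003	5827	k_Bacteria;p_Phylum1;c_Class1;o_Order1;f_Family1;g_Genus1;s_Genus1 species1	bin_G01	9084	1362600	233.8424575253	6171	925650	158.8553286425
G01_C004	9977	k_Bacteria;p_Phylum1;c_Class1;o_Order1;f_Family1;g_Genus1;s_Genus1 species1	bin_G01	15750	2362500	236.7946276436	10874	1631100	163.486017841
G01_C005	6798	k_Bacteria;p_Phylum1;c_Class1;o_Order1;f_Family1;g_Genus1;s_Genus1 species1	bin_G01	10509	1576350	231.8843777582	7298	1094700	161.0326566637
G01_C006	1049	k_Bacteria;p_Phylum1;c_Class1;o_Order1;f_Family1;g_Genus1;s_Genus1 species1	bin_G01	1477	221550	211.2011439466	1114	167100	159.2945662536
G02_C001	4836	k_Bacteria;p_Phylum1;c_Class2;o_Order2;f_Family2;g_Genus2;s_Genus2 species2	bin_G02	1109	166350	34.3982630273	4071	610650	126.2717121588
G02_C002	7776	k_Bacteria;p_Phylum1;c_Class2;o_Order2;f_Family2;g_Genus2;s_Genus2 species2	bin_G02	1753	262950	33.81558641975	6592	988800	127.1604938272
G02_C003	5876	k_Bacteria;p_Phylum1;c_Class2;o_Order2;f_Family2;g_Genus2;s_Genus2 species2	bin_G02	1286	192900	32.82845473111	4939	740850	126.0806671205
G02_C004	6681	k_Bacteria;p_Phylum1;c_Class2;o_Order2;f_Family2;g_Genus2;s_Genus2 species2	bin_G02	1511	226650	33.92456219129	5815	872250	130.5568028738
G02_C005	7728	k_Bacteria;p_Phylum1;c_Class2;o_Order2;f_Family2;g_Genus2;s_Genus2 species2	bin_G02	1713	256950	33.24922360248	6629	994350	128.6684782609
G03_C001	6523	k_Bacteria;p_Phylum2;c_Class3;o_Order3;f_Family3;g_Genus3;s_Genus3 species3	bin_G03	3704	555600	85.17553273034	3380	507000	77.72497317185
G03_C002	10753	k_Bacteria;p_Phylum2;c_Class3;o_Order3;f_Family3;g_Genus3;s_Genus3 species3	bin_G03	6010	901500	83.83706872501	5635	845250	78.60597042686
G03_C003	3512	k_Bacteria;p_Phylum2;c_Class3;o_Order3;f_Family3;g_Genus3;s_Genus3 species3	bin_G03	2010	301500	85.84851936219	1706	255900	72.86446469248
G03_C004	5952	k_Bacteria;p_Phylum2;c_Class3;o_Order3;f_Family3;g_Genus3;s_Genus3 species3	bin_G03	3347	502050	84.3497983871	3202	480300	80.69556451613
G03_C005	5347	k_Bacteria;p_Phylum2;c_Class3;o_Order3;f_Family3;g_Genus3;s_Genus3 species3	bin_G03	3023	453450	84.80456330653	2665	399750	74.76154853189
G03_C006	3758	k_Bacteria;p_Phylum2;c_Class3;o_Order3;f_Family3;g_Genus3;s_Genus3 species3	bin_G03	2069	310350	82.58382118148	1942	291300	77.51463544439
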