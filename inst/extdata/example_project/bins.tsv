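Bin_ID	Method	Tax	Completeness	Contamination	Contigs
bin_G01	synthetic	k_Bacteria;p_Phylum1;c_Class1;o_Order1;f_Family1;g_Genus1;s_Genus1 species1	90.08	1.88	G01_C001|G01_C002|G01_C003|G01_C004|G01_C005|G01_C006
bin_G02	synthetic	k_Bacteria;p_Phylum1;c_Class2;o_Order2;f_Family2;g_Genus2;s_Genus2 species2	99.42	4.81	G02_C001|G02_C002|G02_C003|G02_C004|G02_C005
bin_G03	synthetic	k_Bacteria;p_Phylum2;c_Class3;o_Order3;f_Family3;g_Genus3;s_Genus3 species3	96.32	4.69	G03_C001|G03_C002|G03_C003|G03_C004|G03_C005|G03_C006
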