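{
  "genomes": ["G01", "G02", "G03"],
  "samples": ["S1", "S2"],
  "functions": ["K00001", "K00002", "K00003", "K00004", "K00005", "K00006", "K00007", "K00008", "K00009", "K00010", "K00011", "K00012"],
  "lineages": {
    "G01": "k_Bacteria;p_Phylum1;c_Class1;o_Order1;f_Family1;g_Genus1;s_Genus1 species1",
    "G02": "k_Bacteria;p_Phylum1;c_Class2;o_Order2;f_Family2;g_Genus2;s_Genus2 species2",
    "G03": "k_Bacteria;p_Phylum2;c_Class3;o_Order3;f_Family3;g_Genus3;s_Genus3 species3"
  },
  "abundances": [
    [0.662541397645063, 0.439899075376316],
    [0.0956242476474634, 0.35000626160984],
    [0.241834354707473, 0.210094663013844]
  ],
  "function_copies": [
    [3, 3, 0, 1, 1, 3, 2, 0, 1, 0, 1, 3],
    [1, 3, 0, 3, 0, 0, 2, 1, 1, 1, 3, 2],
    [0, 1, 3, 3, 1, 2, 1, 2, 3, 0, 0, 0]
  ],
  "depth": 100000,
  "mapped_fraction": 0.9,
  "read_length": 150,
  "seed": 42,
  "genome_length_bp": [38790, 31613, 34559],
  "classified_length_bp": [37841, 29304, 33193],
  "function_length_bp": [
    [6093, 5031, 0, 405, 2322, 3896, 3813, 0, 2954, 0, 2351, 5236],
    [1689, 2900, 0, 5707, 0, 0, 2753, 543, 531, 1124, 3265, 5620],
    [0, 2298, 4333, 6833, 1522, 3498, 303, 3213, 5210, 0, 0, 0]
  ]
}
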