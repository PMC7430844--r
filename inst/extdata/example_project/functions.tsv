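DB	ID	Name	Hierarchy
KEGG	K00001	Synthetic enzyme 1	Metabolism;Amino acid metabolism
KEGG	K00002	Synthetic enzyme 2	Metabolism;Amino acid metabolism
KEGG	K00003	Synthetic enzyme 3	Metabolism;Amino acid metabolism
KEGG	K00004	Synthetic enzyme 4	Metabolism;Amino acid metabolism
KEGG	K00005	Synthetic enzyme 5	Metabolism;Carbohydrate metabolism
KEGG	K00006	Synthetic enzyme 6	Metabolism;Carbohydrate metabolism
KEGG	K00007	Synthetic enzyme 7	Metabolism;Carbohydrate metabolism
KEGG	K00008	Synthetic enzyme 8	Metabolism;Carbohydrate metabolism
KEGG	K00009	Synthetic enzyme 9	Metabolism;Energy metabolism
KEGG	K00010	Synthetic enzyme 10	Metabolism;Energy metabolism
KEGG	K00011	Synthetic enzyme 11	Metabolism;Energy metabolism
KEGG	K00012	Synthetic enzyme 12	Metabolism;Energy metabolism
COG	COG0468	RecA/RadA recombinase	Information storage;Replication and repair
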