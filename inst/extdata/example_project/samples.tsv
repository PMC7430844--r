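Sample	Total_reads
S1	100000
S2	100000
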