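lake	design	unassembled_reads	mapped_reads
Lac Paula	SW_A->TS_R	32622245	69318
Lac Paula	SW_A->BS_R	67840581	511831
Lac Paula	TS_A->BS_R	67840581	14234026
Eightmile Lake	SW_A->TS_R	29873977	145692
Eightmile Lake	SW_A->BS_R	29740441	188125
Eightmile Lake	TS_A->BS_R	29740441	1622267
Grand lac Touradi	SW_A->TS_R	29290940	143854
Grand lac Touradi	SW_A->BS_R	30470979	97815
Grand lac Touradi	TS_A->BS_R	30470979	2324829
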