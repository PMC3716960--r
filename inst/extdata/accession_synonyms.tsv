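alias	canonical	note
3328642	33286418	pyruvate kinase muscle isoform M1 consolidated with isoform M2
42716297	355594753	clusterin isoform 1 consolidated with clusterin preproprotein
154146191	153792590	HSP90 alpha isoform 2 consolidated with isoform 1
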