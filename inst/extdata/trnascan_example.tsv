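Sequence		tRNA	Bounds	tRNA	Anti	Intron Bounds	Inf
Name    	tRNA #	Begin	End	Type	Codon	Begin	End	Score
--------	------	-----	----	----	-----	-----	---	------
query    	1	120	196	Leu	TAA	0	0	87.6
query    	2	455	380	Ser	GCT	0	0	66.1
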