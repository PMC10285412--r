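# Inter-subunit bridge registry. positions are author numbers on the named
# component; protein components carry no positions.
bridge	component	positions
mB5	12S	856,858,892
mB5	16S	941
mB5	MRPL14	
mB7	12S	334,335
mB7	MRPL2	
B7a	12S	354
B7a	16S	588
B7b	12S	415,416
B7b	MRPL2	
mB6	MRPS27	
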