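# Mito-ribosomal ligands resolved through the chain map.
name
mRNA
A-tRNA
P-tRNA
E-tRNA
NAD
spermine
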