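# Small-subunit protein registry: assembly/fidelity flags and notable
# residues cited in the structural analysis.
name	fidelity_protein	early_binding	harbors_pathogenic_mutations	notable_residues
MRPS12	1	1	0	Asn34:packing;Lys43:fidelity_equivalent;Arg47:rRNA_contact;Arg55:fidelity_adjacent;Ser86:fidelity_equivalent
MRPS5	1	0	0	Val336:ram
MRPS16	0	1	1	
MRPS22	0	1	1	
MRPS25	0	0	1	
MRPS34	0	1	1	Arg48:rRNA_contact
MRPS27	0	1	0	
MRPS7	0	1	1	Met184:pathogenic;Lys185:rRNA_contact
MRPS14	0	0	1	Arg36:rRNA_contact;Arg102:rRNA_contact;Arg108:pathogenic
MRPS2	0	1	1	Arg100:rRNA_contact
MRPS23	0	1	1	Arg50:rRNA_contact
MRPS17	0	1	0	Lys78:rRNA_contact;Asn44:rRNA_contact
MRPS11	0	0	0	Asn104:rRNA_contact
MRPS21	0	0	0	Lys6:rRNA_contact;Tyr57:rRNA_contact
MRPS37	0	0	0	
MRPS9	0	1	0	
MRPS10	0	0	0	
MRPS29	0	1	0	Arg166:rRNA_contact
MRPS15	0	0	0	
MRPS26	0	0	0	Arg30:rRNA_contact
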