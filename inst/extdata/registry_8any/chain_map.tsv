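# Chain-id map TEMPLATE for the 2.2-A human mito-ribosome model (PDB 8ANY).
# Chain letters are deliberately NOT hardcoded by the package: fill in the
# chain column from your local copy of the structure (auth_asym_id) before
# geometry-mode runs. Entries left as '?' are skipped.
name	chain
12S	?
16S	?
MRPS12	?
MRPS5	?
MRPS16	?
MRPS22	?
MRPS25	?
MRPS34	?
MRPS27	?
MRPS7	?
MRPS14	?
MRPS2	?
MRPS23	?
MRPS17	?
MRPS11	?
MRPS21	?
MRPS37	?
MRPS9	?
MRPS10	?
MRPS29	?
MRPS15	?
MRPS26	?
MRPS18B	?
mRNA	?
A-tRNA	?
P-tRNA	?
E-tRNA	?
NAD	?
spermine	?
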