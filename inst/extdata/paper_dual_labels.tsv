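# Gene/genomic label pairs as printed in the source study's text.
# flagged=1 marks a pair recorded verbatim despite an apparent ref-base
# inconsistency in the original (excluded from round-trip checks).
gene_label	genomic_label	flagged
908A>G	m.1555A>G	0
847C>U	m.1494C>U	0
22U>C	m.669U>C	0
283G>A	m.930G>A	0
139G>A	m.786G>A	0
178U>A	m.825U>A	0
180A>G	m.827A>G	0
295A>G	m.942A>G	0
400A>G	m.1047A>G	0
401C>U	m.1048C>U	0
304G>A	m.951G>A	0
459C>U	m.1106C>U	0
460U>C	m.1107U>C	0
76A>C	m.723A>C	0
145C>U	m.792C>U	0
95U>C	m.742U>C	0
98A>G	m.745A>G	0
209A>G	m.856A>G	0
62G>A	m.709G>A	0
63U>C	m.710U>C	0
65C>A	m.712C>A	0
878C>G	m.1525C>G	0
469A>G	m.1116A>G	0
471A>G	m.1118A>G	0
472U>C	m.1119U>C	0
103G>A	m.750G>A	0
122G>A	m.769G>A	0
123C>U	m.770C>U	0
542U>C	m.1189U>C	0
545C>A	m.1192C>A	0
546U>C	m.1193U>C	0
815G>A	m.1462G>A	0
596U>C	m.1243U>C	0
663C>U	m.1310C>U	0
735A>C	m.1382A>C	0
796U>C	m.1443U>C	0
791G>A	m.1438G>A	0
805U>C	m.1452U>C	0
806A>G	m.1453A>G	0
333U>C	m.980U>C	0
358U>C	m.1005U>C	0
360G>A	m.1007G>A	0
361A>G	m.1008A>G	0
341G>A	m.988G>A	0
343U>C	m.990U>C	0
448U>C	m.1095U>C	0
856G>A	m.1503G>A	0
861C>U	m.1508C>U	0
890C>U	m.1537C>U	0
533U>G	m.1180U>G	0
826C>U	m.1473C>U	0
579C>G	m.1226C>G	0
684A>G	m.1331A>G	0
910A>C	m.1557A>C	0
951G>A	m.1598G>A	0
141A>G	m.1811A>G	0
281A	m.928A	0
280G	m.927G	0
290U	m.937U	0
588A	m.2258A	0
941U	m.2611T	0
947A	m.1594G	1
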