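# 12S mt-rRNA secondary-structure pairs (gene-relative, 1-based) digitized
# for the positions the curated table uses. provenance=text: helix
# membership stated in the study's narrative; provenance=inferred: pair
# read off the published map image without textual confirmation.
# terminal=1 marks a pair closing a helix end or loop.
i	j	helix	terminal	provenance
22	281	h3	0	text
109	139	h11	0	text
145	149	h12	1	text
85	95	h7	0	text
183	209	h15	1	text
77	103	h7	0	text
304	396	h20	0	text
294	486	h19	0	inferred
544	816	h28	0	text
545	815	h28	1	text
596	699	h32	0	text
663	668	h38	1	text
723	735	h41	1	text
790	806	h43	0	text
791	805	h43	0	text
533	827	h28	0	text
534	826	h28	0	text
333	361	h23	1	text
334	360	h23	0	text
341	352	h23	0	text
343	350	h23	0	text
336	358	h23	0	text
413	448	h24	0	text
861	895	h44	0	text
847	908	h44	0	text
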