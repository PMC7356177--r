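# Published candidate table from a fibromyalgia PBMC expression study:
# five modulated lncRNAs with their signed linear fold changes, counts of
# targeted miRNAs / targeted coding DEGs / module-associated targeted DEGs,
# and the labels of the six-module DEG network regions their targets reach.
lnc_id	fc	n_mirnas	n_degs	n_module_degs	modules
CTD-2651B20.6	5.23	2	12	4	M3 M5 M6
RP1-151F17.1	4.65	15	75	16	M2 M3 M4 M5 M6
AC009299.3	-4.52	29	183	38	M1 M2 M3 M4 M5 M6
RP11-283I3.6	-5.05	1	0	0	none
RP11-747H7.3	-9	8	57	12	M1 M2 M3 M4 M5 M6
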