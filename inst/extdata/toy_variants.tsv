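sample	contig	pos	ref	alt	vaf
iso1	chrI	13	C	A	0.97
iso1	chrI	20	G	T	1
iso1	chrI	16	C	A	0.95
iso1	chrI	4	C	A	0.4
iso1	chrI	23	C	A	0.98
iso2	chrI	32	C	A	0.96
iso2	chrI	17	C	A	0.93
iso2	chrI	23	C	A	0.99
iso2	chrI	9	G	T	0.95
iso2	chrI	40	C	CT	0.95
iso3	chrI	45	C	T	1
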