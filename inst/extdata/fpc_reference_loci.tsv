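locus	type	source
chr12:130382166-130686668	deletion	Al-Sukhni 2012
chr3:60219748-60263116	deletion	Lucito 2007
chr18:6838462-7291170	duplication	Al-Sukhni 2012
chr9:2235919-2351848	deletion	Al-Sukhni 2012
chr11:39882017-40010124	deletion	Al-Sukhni 2012
chr19:2984601-5201290	duplication	Lucito 2007
chr7:133223330-133393933	duplication	Al-Sukhni 2012
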