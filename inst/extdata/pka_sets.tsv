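set	group	pka	type
emboss	Nterm	8.6	basic
emboss	Cterm	3.6	acidic
emboss	C	8.5	acidic
emboss	D	3.9	acidic
emboss	E	4.1	acidic
emboss	H	6.5	basic
emboss	K	10.8	basic
emboss	R	12.5	basic
emboss	Y	10.1	acidic
lehninger	Nterm	9.69	basic
lehninger	Cterm	2.34	acidic
lehninger	C	8.33	acidic
lehninger	D	3.86	acidic
lehninger	E	4.25	acidic
lehninger	H	6.0	basic
lehninger	K	10.53	basic
lehninger	R	12.48	basic
lehninger	Y	10.07	acidic
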