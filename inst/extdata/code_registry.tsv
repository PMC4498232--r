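key	seq_class	gi	organism	labeling	kind	primitive	generator
S02.a	TS	45269853	Saccharomyces cerevisiae	D	F	x^3+ax^2+bx+b	x^6+x^5+1
S02.b	TS	45269853	Saccharomyces cerevisiae	B	R	x^6+x^4+x^3+x+1	x^6+2x^5+x^4+x^3+3x+1
S02.c	TS*	78096542	Triticum aestivum	D	F	x^3+bx^2+x+a	x^6+x^5+x^4+x+1
S02.d	TS*	78096542	Triticum aestivum	C	R	x^6+x^5+x^4+x+1	x^6+x^5+x^4+2x^2+3x+1
S02.e	TS*	632733	Nicotiana tabacum	A	R	x^6+x^5+x^2+x+1	x^6+3x^5+2x^4+x^2+x+1
S02.f	TS*	632733	Nicotiana tabacum	A	R	x^6+x^5+x^3+x^2+1	x^6+3x^5+x^3+x^2+2x+1
S02.g	TS	7328566	Citrus sinensis	B	R	x^6+x^5+1	x^6+3x^5+2x^3+1
S02.h	TS*	186509758	Arabidopsis thaliana	A	R	x^6+x^5+x^3+x^2+1	x^6+3x^5+x^3+x^2+2x+1
S02.i	PM	832917	Saccharomyces cerevisiae	A	R	x^6+x^5+x^2+x+1	x^6+3x^5+2x^4+x^2+x+1
S02.j	TS	12587	Homo sapiens	C	R	x^6+x^5+1	x^6+3x^5+2x^3+1
MDH	?	30695458	Arabidopsis thaliana	C	R	x^10+x^9+x^8+x^7+x^6+x^4+x^3+x+1	x^10+x^9+x^8+3x^7+x^6+x^4+x^3+3x+1
3.a	TS	217937	Ipomoea batatas	B	R	x^3+ax^2+ax+a	x^6+x^5+x^3+x^2+1
3.b	TS	51093376	Polistes dominulus	D	F	x^3+ax^2+bx+b	x^6+x^5+1
3.c	TS	16740522	Mesobuthus martensii	A	R	x^6+x^5+x^4+x+1	x^6+x^5+x^4+2x^2+3x+1
3.d	?	25140446	Homo sapiens	B	R	x^6+x^5+1	x^6+3x^5+2x^3+1
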