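sample_id	family_id	relationship	sex	haplotype	Id-01	Id-02	Id-03	Id-04	Id-05	Id-06	Id-07	Id-08	Id-9	Id-10	Id-11
207	fam01	Father	Male	Gj2	W Homo	WD Hetero	I Homo	W Homo	WD Hetero	WD Hetero	W Homo	W Homo	W Homo	WD Hetero	W Homo
352	fam01	Sibling of 207	Male	Gj2	W Homo	WD Hetero	I Homo	W Homo	WD Hetero	WD Hetero	W Homo	W Homo	W Homo	W Homo	W Homo
387	fam01	Ditto	Female	Gj2	W Homo	W Homo	I Homo	W Homo	WD Hetero	W Homo	W Homo	W Homo	W Homo	WD Hetero	WD Hetero
388	fam01	Ditto	Female	Gj2	W Homo	WD Hetero	I Homo	W Homo	W Homo	WD Hetero	W Homo	W Homo	W Homo	W Homo	W Homo
213	fam02	Mother	Female	Gj2	W Homo	W Homo	W Homo	W Homo	W Homo	W Homo	WD Hetero	W Homo	W Homo	WD Hetero	W Homo
374	fam02	Sibling of 213	Female	Gj2	W Homo	W Homo	W Homo	W Homo	WD Hetero	W Homo	W Homo	W Homo	W Homo	WD Hetero	W Homo
T73/R568	fam03	Father of 116-390	Male	Gj2	W Homo	WD Hetero	WI Hetero	W Homo	WD Hetero	W Homo	WD Hetero	WD Hetero	W Homo	W Homo	W Homo
116	fam03	Mother of 358, 359	Female	Gj2	WD Hetero	W Homo	W Homo	W Homo	D Homo	W Homo	W Homo	D Homo	W Homo	WD Hetero	WD Hetero
204	fam03	Sibling of T73	Female	Gj2	WD Hetero	WD Hetero	I Homo	W Homo	W Homo	W Homo	WD Hetero	W Homo	W Homo	W Homo	WD Hetero
261	fam03	Ditto	Female	Gj2	WD Hetero	W Homo	W Homo	W Homo	WD Hetero	W Homo	WD Hetero	D Homo	W Homo	W Homo	W Homo
312	fam03	Ditto	Female	Gj2	WD Hetero	W Homo	W Homo	W Homo	WD Hetero	W Homo	WD Hetero	D Homo	W Homo	WD Hetero	WD Hetero
313	fam03	Ditto	Female	Gj2	WD Hetero	WD Hetero	W Homo	W Homo	WD Hetero	W Homo	WD Hetero	W Homo	W Homo	W Homo	W Homo
353	fam03	Ditto	Male	Gj2	WD Hetero	WD Hetero	I Homo	W Homo	WD Hetero	W Homo	WD Hetero	WD Hetero	W Homo	W Homo	W Homo
390	fam03	Ditto	Female	Gj2	WD Hetero	WD Hetero	W Homo	W Homo	D Homo	W Homo	W Homo	D Homo	W Homo	WD Hetero	W Homo
253	fam03	Grandsibling of T73	Male	Gj2	WD Hetero	W Homo	WI Hetero	W Homo	WD Hetero	W Homo	D Homo	WD Hetero	W Homo	W Hetero	W Homo
384	fam03	Ditto	Female	Gj2	WD Hetero	W Homo	W Homo	W Homo	WD Hetero	W Homo	D Homo	W Homo	W Homo	W Hetero	W Homo
358	fam03	Ditto	Male	Gj2	W Homo	W Homo	W Homo	W Homo	WD Hetero	W Homo	W Homo	WD Hetero	W Homo	WD Hetero	WD Hetero
359	fam03	Ditto	Female	Gj2	W Homo	W Homo	W Homo	W Homo	WD Hetero	W Homo	W Homo	W Homo	W Homo	WD Hetero	WD Hetero
123	fam04	Father	Male	Gj1	W Homo	W Homo	W Homo	W Homo	WD Hetero	W Homo	W Homo	W Homo	W Homo	W Homo	W Homo
131	fam04	Mother	Female	Gj2	WD Hetero	WD Hetero	I Homo	W Homo	W Homo	W Homo	W Homo	W Homo	W Homo	W Homo	W Homo
244	fam04	Sibling of 123 and 131	Male	Gj2	W Homo	W Homo	WI Hetero	W Homo	WD Hetero	W Homo	W Homo	W Homo	W Homo	W Homo	W Homo
245	fam04	Twins of 244	Female	Gj2	W Homo	WD Hetero	W Homo	W Homo	WD Hetero	W Homo	W Homo	W Homo	W Homo	W Homo	W Homo
211	fam05	Father	Male	Gj2	W Homo	W Homo	W Homo	W Homo	W Homo	WD Hetero	W Homo	WD Hetero	W Homo	W Homo	W Homo
362	fam05	Sibling of 211	Male	Gj1	W Homo	W Homo	WI Hetero	W Homo	W Homo	D Homo	W Homo	WD Hetero	W Homo	WD Hetero	W Homo
315	fam06	Twins of 316	Female	Gj2	WD Hetero	WD Hetero	I Homo	WD Hetero	WD Hetero	W Homo	D Homo	W Homo	WD Hetero	W Homo	WD Hetero
316	fam06	Twins of 315	Male	Gj2	W Homo	W Homo	WI Hetero	WD Hetero	W Homo	W Homo	WD Hetero	WD Hetero	W Homo	W Homo	WD Hetero
201	fam07	Father	Male	Gj2	WD Hetero	D Homo	W Homo	W Homo	W Homo	WD Hetero	W Homo	W Homo	WD Hetero	WD Hetero	W Homo
375	fam07	Sibling of 201	Female	Gj2	W Homo	WD Hetero	W Homo	W Homo	W Homo	WD Hetero	W Homo	W Homo	W Homo	WD Hetero	W Homo
63	fam08	Mother	Female	Gj2	W Homo	WD Hetero	W Homo	WD Hetero	W Homo	W Homo	WD Hetero	W Homo	W Homo	WD Hetero	W Homo
169	fam08	Sibling of 63	Male	Gj2	W Homo	WD Hetero	W Homo	W Homo	W Homo	WD Hetero	WD Hetero	W Homo	WD Hetero	WD Hetero	W Homo
109	fam09	Mother	Female	Gj2	W Homo	WD Hetero	W Homo	W Homo	WD Hetero	W Homo	WD Hetero	W Homo	WD Hetero	WD Hetero	W Homo
392	fam09	Sibling of 109	Female	Gj2	W Homo	WD Hetero	I Homo	W Homo	D Homo	WD Hetero	WD Hetero	W Homo	W Homo	W Homo	W Homo
T74/R566	fam10	Father	Male	-	WD Hetero	WD Hetero	W Homo	W Homo	W Homo	W Homo	W Homo	W Homo	WD Hetero	WD Hetero	W Homo
124	fam10	Sibling of T74	Female	Gj1	W Homo	D Homo	W Homo	W Homo	WD Hetero	W Homo	W Homo	W Homo	W Homo	WD Hetero	W Homo
125	fam10	Ditto	Male	Gj1	WD Hetero	WD Hetero	W Homo	W Homo	WD Hetero	W Homo	W Homo	W Homo	WD Hetero	W Homo	W Homo
251	fam11	Mother	Female	Gj2	W Homo	W Homo	W Homo	W Homo	W Homo	W Homo	WD Hetero	W Homo	W Homo	W Homo	W Homo
415	fam11	Sibling of 251	Male	Gj2	W Homo	W Homo	WI Hetero	W Homo	WD Hetero	WD Hetero	WD Hetero	W Homo	WD Hetero	W Homo	W Homo
271	fam12	Father	Male	Gj2	W Homo	W Homo	W Homo	W Homo	W Homo	W Homo	W Homo	WD Hetero	WD Hetero	W Homo	W Homo
420	fam12	Sibling of 271	Female	Gj1	W Homo	W Homo	W Homo	W Homo	W Homo	W Homo	W Homo	W Homo	WD Hetero	W Homo	W Homo
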