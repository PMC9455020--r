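sample_id	region	sex	haplotype	Id-01	Id-02	Id-03	Id-04	Id-05	Id-06	Id-07	Id-08	Id-9	Id-10	Id-11
70	Kushiro	Female	Gj2	W Homo	D Homo	WI Hetero	W Homo	W Homo	WD Hetero	D Homo	W Homo	W Homo	W Homo	W Homo
89	Kushiro	Female	Gj1	W Homo	W Homo	WI Hetero	W Homo	WD Hetero	WD Hetero	WD Hetero	W Homo	W Homo	WD Hetero	W Homo
123	Kushiro	Male	Gj1	W Homo	W Homo	W Homo	W Homo	WD Hetero	W Homo	W Homo	W Homo	W Homo	W Homo	W Homo
150	Kushiro	Male	Gj2	W Homo	WD Hetero	I Homo	W Homo	WD Hetero	W Homo	WD Hetero	WD Hetero	W Homo	WD Hetero	W Homo
194	Kushiro	Female	Gj1	W Homo	W Homo	W Homo	W Homo	WD Hetero	W Homo	D Homo	W Homo	W Homo	W Homo	W Homo
211	Kushiro	Male	Gj2	W Homo	W Homo	W Homo	W Homo	W Homo	WD Hetero	W Homo	WD Hetero	W Homo	W Homo	W Homo
247	Kushiro	Male	Gj2	W Homo	D Homo	W Homo	W Homo	W Homo	W Homo	WD Hetero	WD Hetero	W Homo	WD Hetero	W Homo
251	Kushiro	Female	Gj2	W Homo	W Homo	W Homo	W Homo	W Homo	W Homo	WD Hetero	W Homo	W Homo	W Homo	W Homo
271	Kushiro	Male	Gj2	W Homo	W Homo	W Homo	W Homo	W Homo	W Homo	W Homo	WD Hetero	WD Hetero	W Homo	W Homo
315	Kushiro	Female	Gj2	WD Hetero	WD Hetero	I Homo	WD Hetero	WD Hetero	W Homo	D Homo	W Homo	WD Hetero	W Homo	WD Hetero
344	Kushiro	Male	Gj2	W Homo	W Homo	WI Hetero	W Homo	W Homo	WD Hetero	W Homo	WD Hetero	WD Hetero	WD Hetero	W Homo
361	Kushiro	Male	Gj2	W Homo	D Homo	W Homo	W Homo	W Homo	WD Hetero	WD Hetero	W Homo	W Homo	W Homo	W Homo
362	Kushiro	Male	Gj1	W Homo	W Homo	WI Hetero	W Homo	W Homo	D Homo	W Homo	WD Hetero	W Homo	WD Hetero	W Homo
54	Nemuro	Male	Gj2	W Homo	W Homo	WI Hetero	W Homo	W Homo	WD Hetero	WD Hetero	WD Hetero	W Homo	WD Hetero	W Homo
72	Nemuro	Female	Gj2	W Homo	W Homo	WI Hetero	W Homo	WD Hetero	W Homo	WD Hetero	W Homo	W Homo	WD Hetero	W Homo
127	Nemuro	Male	Gj2	W Homo	W Homo	WI Hetero	W Homo	WD Hetero	WD Hetero	WD Hetero	W Homo	W Homo	WD Hetero	W Homo
137	Nemuro	Male	Gj2	W Homo	W Homo	WI Hetero	W Homo	W Homo	WD Hetero	WD Hetero	WD Hetero	W Homo	D Homo	W Homo
139	Nemuro	Female	Gj2	W Homo	W Homo	W Homo	W Homo	W Homo	WD Hetero	W Homo	W Homo	W Homo	W Homo	W Homo
223	Nemuro	Male	Gj2	WD Hetero	WD Hetero	W Homo	WD Hetero	W Homo	WD Hetero	WD Hetero	WD Hetero	W Homo	D Homo	W Homo
280	Nemuro	Female	Gj2	W Homo	WD Hetero	W Homo	WD Hetero	W Homo	W Homo	W Homo	W Homo	W Homo	WD Hetero	W Homo
287	Nemuro	Female	Gj2	WD Hetero	W Homo	W Homo	W Homo	WD Hetero	W Homo	WD Hetero	W Homo	W Homo	D Homo	W Homo
319	Nemuro	Male	Gj2	W Homo	WD Hetero	W Homo	WD Hetero	WD Hetero	W Homo	W Homo	W Homo	W Homo	D Homo	W Homo
330	Nemuro	Female	Gj2	W Homo	D Homo	I Homo	W Homo	W Homo	WD Hetero	D Homo	D Homo	W Homo	W Homo	W Homo
331	Nemuro	Female	Gj2	W Homo	WD Hetero	I Homo	W Homo	W Homo	WD Hetero	W Homo	W Homo	W Homo	W Homo	W Homo
396	Nemuro	Female	Gj2	W Homo	WD Hetero	I Homo	W Homo	WD Hetero	WD Hetero	W Homo	D Homo	W Homo	D Homo	W Homo
397	Nemuro	Female	Gj2	W Homo	W Homo	W Homo	W Homo	W Homo	D Homo	WD Hetero	W Homo	W Homo	W Homo	W Homo
63	Tokachi	Female	Gj2	W Homo	WD Hetero	W Homo	WD Hetero	W Homo	W Homo	WD Hetero	W Homo	W Homo	WD Hetero	W Homo
71	Tokachi	Female	Gj2	W Homo	D Homo	I Homo	W Homo	WD Hetero	W Homo	WD Hetero	W Homo	W Homo	W Homo	W Homo
78	Tokachi	Male	Gj2	W Homo	W Homo	WI Hetero	W Homo	W Homo	W Homo	WD Hetero	W Homo	W Homo	W Homo	D Homo
109	Tokachi	Female	Gj2	W Homo	WD Hetero	W Homo	W Homo	WD Hetero	W Homo	WD Hetero	W Homo	WD Hetero	WD Hetero	W Homo
131	Tokachi	Female	Gj2	WD Hetero	WD Hetero	I Homo	W Homo	W Homo	W Homo	W Homo	W Homo	W Homo	W Homo	W Homo
187	Tokachi	Male	Gj2	W Homo	W Homo	WI Hetero	W Homo	W Homo	W Homo	W Homo	W Homo	W Homo	W Homo	W Homo
201	Tokachi	Male	Gj2	WD Hetero	D Homo	W Homo	W Homo	W Homo	WD Hetero	W Homo	W Homo	WD Hetero	WD Hetero	W Homo
207	Tokachi	Male	Gj2	W Homo	WD Hetero	I Homo	W Homo	WD Hetero	WD Hetero	W Homo	W Homo	W Homo	WD Heter	W Homo
213	Tokachi	Female	Gj2	W Homo	W Homo	W Homo	W Homo	W Homo	W Homo	WD Hetero	W Homo	W Homo	WD Heter	W Homo
254	Tokachi	Female	Gj2	WD Hetero	WD Hetero	W Homo	W Homo	WD Hetero	W Homo	W Homo	D Homo	WD Hetero	W Homo	WD Hetero
256	Tokachi	Female	Gj2	W Homo	W Homo	WI Hetero	W Homo	W Homo	W Homo	W Homo	D Homo	W Homo	W Homo	WD Hetero
371	Tokachi	Male	Gj1	WD Hetero	WD Hetero	W Homo	W Homo	WD Hetero	W Homo	W Homo	W Homo	WD Hetero	WD Heter	W Homo
373	Tokachi	Female	Gj1	WD Hetero	W Homo	W Homo	W Homo	W Homo	WD Hetero	WD Hetero	W Homo	WD Hetero	WD Heter	W Homo
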