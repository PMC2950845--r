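protein_number	group	hits	reference_size
23	1	13	26
25	1	26	26
33	1	26	26
37	1	13	26
40	1	26	26
41	1	24	26
43	1	19	26
46	1	26	26
56	1	16	26
62	1	14	26
65	1	26	26
94	1	26	26
1	2	26	26
2	2	26	26
3	2	26	26
4	2	26	26
5	2	26	26
6	2	25	26
9	2	26	26
42	2	25	26
50	2	20	26
63	2	18	26
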