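position	ref	alt	rs_id	score_35id	score_20id	cluster	pathogenic
106	L	S	rs104894105	7	7		yes
122	D	Y	rs142157346	1	6		yes
130	G	V	rs104894107	6	8		yes
146	N	K	rs146818694	9	9	C2	yes
148	Q	R	rs140472905	9	9	C2	yes
154	I	F	rs104894106	9	9	C1	yes
155	W	R	rs138471431	9	9	C2	yes
156	L	P	rs143340609	6	7		yes
165	R	C	rs138034837	7	9	C2	yes
173	W	G	rs56214919	9	9	C1	yes
182	L	F	rs139616452	9	8	C1	yes
182	L	H	rs149335881	9	8	C1	yes
183	H	R	rs144610605	3	1		yes
186	L	R	rs148443992	9	9	C1	yes
198	L	R	rs144104124	5	5		yes
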