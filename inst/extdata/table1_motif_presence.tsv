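sequence	Y143	S158	S161	E189	organism	taxon_group
FRDA_HUMAN	yes	yes	yes	yes	Homo sapiens	eukaryote
FRDA_BOVIN	yes	yes	yes	yes	Bos taurus	eukaryote
FRDA_MOUSE	yes	yes	yes	yes	Mus musculus	eukaryote
FRDA_RAT	yes	G	yes	yes	Rattus norvegicus	eukaryote
FRDA_DROME	yes	yes	yes	yes	Drosophila melanogaster	eukaryote
FRDA_CAEEL	yes	yes	yes	yes	Caenorhabditis elegans	eukaryote
FRDA_ARATH	yes	yes	yes	yes	Arabidopsis thaliana	eukaryote
FRDA_SCHPO	yes	yes	yes	yes	Schizosaccharomyces pombe	eukaryote
FRDA_DICDI	yes	yes	yes	yes	Dictyostelium discoideum	eukaryote
FRDA_YEAST	yes	yes	yes	yes	Saccharomyces cerevisiae	eukaryote
CYAY_RICAE	yes	yes	yes	yes	Rickettsia africae	rickettsia
CYAY_RICFE	yes	yes	yes	yes	Rickettsia felis	rickettsia
FRDA_ENCCU	yes	yes	T	yes	Encephalitozoon cuniculi	eukaryote
CYAY_NEIMB	I	A	G	A	Neisseria meningitidis serogroup B	bacteria
CYAY_JANMA	I	A	G	M	Janthinobacterium sp.	bacteria
CYAY_RICBR	yes	yes	yes	yes	Rickettsia bellii	rickettsia
CYAY_RICAH	yes	yes	yes	yes	Rickettsia akari	rickettsia
CYAY_AZOVD	L	A	G	V	Azotobacter vinelandii	bacteria
CYAY_RICTY	yes	yes	yes	yes	Rickettsia typhi	rickettsia
CYAY_PSEPG	L	D	G	I	Pseudomonas putida	bacteria
CYAY_TOLAT	I	T	N	A	Tolumonas auensis	bacteria
CYAY_SALPK	I	T	yes	A	Salmonella paratyphi A	bacteria
CYAY_PSEPF	L	A	G	I	Pseudomonas fluorescens	bacteria
CYAY_THISH	L	yes	G	-	Thioalkalivibrio sulfidiphilus	bacteria
CYAY_SALA4	I	T	G	A	Salmonella agona	bacteria
CYAY_AERS4	V	T	N	A	Aeromonas salmonicida	bacteria
CYAY_ECO81	I	T	G	A	Escherichia coli O81	bacteria
CYAY_EDWI9	I	T	G	-	Edwardsiella ictaluri	bacteria
CYAY_ALISL	I	yes	G	yes	Aliivibrio salmonicida	bacteria
CYAY_CHLT3	yes	E	N	L	Chloroherpeton thalassium	bacteria
CYAY_PSEF5	V	A	G	I	Pseudomonas fluorescens	bacteria
CYAY_VIBCH	I	yes	G	yes	Vibrio cholerae serotype O1	bacteria
CYAY_PSEU2	L	A	G	F	Pseudomonas syringae pv. syringae	bacteria
CYAY_PSESM	L	A	G	M	Pseudomonas syringae pv. tomato	bacteria
CYAY_VIBPA	I	yes	G	yes	Vibrio parahaemolyticus serotype O3:K6	bacteria
CYAY_VIBVU	I	yes	G	yes	Vibrio vulnificus	bacteria
CYAY_ALIFM	I	yes	G	yes	Aliivibrio fischeri	bacteria
CYAY_PSEPW	L	D	G	I	Pseudomonas putida	bacteria
CYAY_VIBTL	I	yes	G	yes	Vibrio atlanticus	bacteria
CYAY_PSEFS	L	A	G	L	Pseudomonas fluorescens	bacteria
CYAY_PHOLL	I	T	G	A	Photorhabdus laumondii subsp. laumondii	bacteria
CYAY_HERAR	I	T	G	-	Herminiimonas arsenicoxydans	bacteria
CYAY_CROS8	I	T	G	A	Cronobacter sakazakii	bacteria
CYAY_SALNS	I	T	G	A	Salmonella newport	bacteria
CYAY_PSEAE	L	A	G	-	Pseudomonas aeruginosa	bacteria
CYAY_ENT38	I	T	G	A	Enterobacter sp.	bacteria
CYAY_DICCH	I	T	G	A	Dickeya chrysanthemi	bacteria
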