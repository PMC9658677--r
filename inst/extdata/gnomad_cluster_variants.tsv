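cluster	position	ref	alt	frequency	dataset	pathogenic	rs_id
C1	154	I	F	7.42e-06	gnomAD_v3.1.1_non_neuro	yes	
C1	154	I	F	8.72e-06	gnomAD_v2.1.1_non_neuro	yes	
C1	154	I	V	7.42e-06	gnomAD_v3.1.1_non_neuro	no	
C1	154	I	V	9.41e-05	gnomAD_v2.1.1_non_neuro	no	
C2	133	T	A	7.42e-06	gnomAD_v3.1.1_non_neuro	no	
C2	133	T	A	1.922e-05	gnomAD_v2.1.1_non_neuro	no	
C3	158	S	P	7.42e-06	gnomAD_v3.1.1_non_neuro	no	
C3	158	S	P	4.703e-05	gnomAD_v2.1.1_non_neuro	no	
C3	161	S	R	7.42e-06	gnomAD_v3.1.1_non_neuro	no	
acidic_ridge	112	D	Y	9.61e-06	gnomAD_v2.1.1_non_neuro	no	
acidic_ridge	112	D	H	7.42e-06	gnomAD_v3.1.1_non_neuro	no	
acidic_ridge	100	E	A	9.65e-05	gnomAD_v3.1.1_non_neuro	no	
acidic_ridge	100	E	A	2.4505e-04	gnomAD_v2.1.1_non_neuro	no	
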