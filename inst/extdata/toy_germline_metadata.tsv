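id	locus	segment_type	functionality	anchor_offset	reading_frame	cdr1_start	cdr1_end	cdr2_start	cdr2_end
IGHV1-2*01	IGH	V	functional	291	0	75	99	150	174
IGHV3-11*01	IGH	V	functional	291	0	75	99	150	174
IGHV3-23*01	IGH	V	functional	291	0	75	99	150	174
IGHV4-34*01	IGH	V	functional	291	0	75	99	150	174
IGHV3-9*01	IGH	V	pseudogene	291	0	75	99	150	174
IGHD1-26*01	IGH	D	functional	NA	NA	NA	NA	NA	NA
IGHD3-10*01	IGH	D	functional	NA	NA	NA	NA	NA	NA
IGHD6-19*01	IGH	D	functional	NA	NA	NA	NA	NA	NA
IGHJ4*01	IGH	J	functional	9	0	NA	NA	NA	NA
IGHJ6*01	IGH	J	functional	9	0	NA	NA	NA	NA
IGKV1-39*01	IGK	V	functional	291	0	75	99	150	174
IGKV1-5*01	IGK	V	functional	291	0	75	99	150	174
IGKV3-20*01	IGK	V	functional	291	0	75	99	150	174
IGKJ1*01	IGK	J	functional	9	0	NA	NA	NA	NA
IGKJ2*01	IGK	J	functional	9	0	NA	NA	NA	NA
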