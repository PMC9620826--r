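disease_id	hpo_term_id	gene	inheritance	provisional
OMIM:219700	HP:0006528	CFTR	autosomal recessive	FALSE
OMIM:219700	HP:0002205	CFTR	autosomal recessive	FALSE
OMIM:219700	HP:0001508	CFTR	autosomal recessive	FALSE
OMIM:219700	HP:0002024	CFTR	autosomal recessive	FALSE
OMIM:219700	HP:0009999	CFTR	autosomal recessive	FALSE
OMIM:613490	HP:0001399	SERPINA1	autosomal recessive	FALSE
OMIM:613490	HP:0002097	SERPINA1	autosomal recessive	FALSE
OMIM:613490	HP:0012735	SERPINA1	autosomal recessive	FALSE
OMIM:613490	HP:0006532	SERPINA1	autosomal recessive	FALSE
OMIM:613490	HP:0003010	SERPINA1	autosomal recessive	FALSE
OMIM:174900	HP:0002014	SMAD4	autosomal dominant	FALSE
OMIM:174900	HP:0002580	SMAD4	autosomal dominant	FALSE
OMIM:174900	HP:0004396	SMAD4	autosomal dominant	FALSE
OMIM:145600	HP:0002189	RYR1	autosomal dominant	FALSE
OMIM:145600	HP:0001249	RYR1	multifactorial	FALSE
OMIM:145600	HP:0011675	RYR1	autosomal dominant	FALSE
OMIM:145600	HP:0000822	RYR1	autosomal dominant	FALSE
OMIM:999001	HP:0001903	KRAS	somatic	FALSE
OMIM:999001	HP:0002716	KRAS	somatic	FALSE
OMIM:999001	HP:0001249	KRAS	somatic	FALSE
OMIM:999002	HP:0002189	GENE2	autosomal dominant	TRUE
OMIM:999002	HP:0000822	GENE2	autosomal dominant	TRUE
OMIM:999002	HP:0011675	GENE2	autosomal dominant	TRUE
OMIM:999003	HP:0000822	GENE3	autosomal recessive	FALSE
OMIM:999003	HP:0011675	GENE3	autosomal recessive	FALSE
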