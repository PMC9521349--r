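patient_id	gene	alteration_class	significance
PT001	BRCA1	frameshift	unclassified
PT001	NOTCH1	missense	pathogenic
PT002	BRCA2	nonsense	vus
PT002	TP53	missense	likely_pathogenic
PT003	TP53	missense	vus
PT003	AR	amplification	pathogenic
PT004	BRCA1	splice	pathogenic
PT004	ERBB2	missense	pathogenic
PT005	ATM	missense	benign
PT005	PIK3CA	missense	pathogenic
PT006	BRCA2	frameshift	pathogenic
PT006	BRCA2	frameshift	pathogenic
PT007	EGFR	missense	vus
PT008	TP53	nonsense	unclassified
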