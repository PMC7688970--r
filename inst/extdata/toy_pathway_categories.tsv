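pathway_id	category
PW_TCR_SIGNALING	Immune System
PW_BCR_SIGNALING	Immune System
PW_NK_CYTOTOXICITY	Immune System
PW_PHAGOCYTOSIS	Immune System
PW_LEUKEMIA	Immune Diseases
PW_VIRAL_INFECTION	Infectious Diseases
PW_GLYCOLYSIS	Metabolism
PW_OXPHOS	Metabolism
PW_SPLICEOSOME	Genetic Information Processing
PW_RIBOSOME	Genetic Information Processing
PW_CELL_CYCLE	Genetic Information Processing
PW_MISC_DISEASE	Other
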