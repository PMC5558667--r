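# Default IUPAC promoter motif dictionary.
# TGACG-motif is literal; DRE core from the dehydration-response literature.
# Other elements (ABRE, TCA-element, HSE) are database-internal matrices and
# must be supplied by the user as IUPAC consensus strings.
motif_name	iupac
TGACG-motif	TGACG
DRE-core	RCCGAC
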