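# Default code sets for the tiered advanced-CKD phenotype.
#
# advanced_ckd and aki are the standard ICD-10 categories. The dialysis set
# is a SYNTHETIC stand-in: dialysis/ESKD exclusion lists are maintained
# locally by health systems, so replace this block with your own codes.
# ICD-10 entries match as dot-normalized prefixes; CPT entries match exactly
# and may be written as inclusive 5-digit ranges ("90935-90999").
advanced_ckd:
  icd10: ["N18.4", "N18.5"]
aki:
  icd10: ["N17"]
dialysis:
  icd10: ["Z99.2", "N18.6", "Z49"]
  cpt: ["90935-90999"]
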