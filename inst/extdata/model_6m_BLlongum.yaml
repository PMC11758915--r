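# Abundance model: B. longum subsp. longum at six months (9 features).
# Small cohort at this age group: leave-one-out cross-validation.
response: BLlongum
timepoint: 6m
cv:
  scheme: loocv
features:
  - maternal_abundance:BLlongum
  - strain_shared:BLlongum
  - abundance_1m:BLlongum
  - feeding_type
  - feeding_frequency
  - bifido_diversity
  - presence:B.adolescentis
  - presence:B.bifidum
  - presence:B.breve
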