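# Abundance model: B. longum subsp. infantis at six months (8 features).
response: BLinfantis
timepoint: 6m
cv:
  scheme: loocv
features:
  - abundance_1m:BLlongum
  - feeding_type
  - feeding_frequency
  - bifido_diversity
  - presence:B.breve
  - presence:B.pseudocatenulatum
  - abundance:B.bifidum
  - abundance:B.adolescentis
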