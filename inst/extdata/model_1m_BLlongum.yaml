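# Abundance model: B. longum subsp. longum at one month (9 features).
# Feature lists are templates for the kind of covariates such models use
# (maternal effects, transmission, nutrition, interspecies interactions);
# they are not a verbatim reproduction of any cohort's feature set.
response: BLlongum
timepoint: 1m
cv:
  scheme: repeated_kfold
  nfolds: 10
  repeats: 10
features:
  - maternal_abundance:BLlongum
  - strain_shared:BLlongum
  - feeding_type
  - feeding_frequency
  - bifido_diversity
  - abundance:B.breve
  - abundance:B.pseudocatenulatum
  - presence:B.adolescentis
  - presence:B.bifidum
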