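# Default Obol-style grammar configuration for phenotype label parsing.
# Productions are applied in this priority order; see ?default_grammar.
productions:
  - quality_bearer
  - quality_of_bearer
  - abnormal_morphology
  - abnormal_bearer
  - compound_bearer
  - absent_bearer
role_priority:
  - gross-anatomy
  - cell
  - cell-component
  - process
  - chemical
irregular_plurals:
  teeth: tooth
  feet: foot
  ganglia: ganglion
  vertebrae: vertebra
  testes: testis
  ossicles: ossicle
  vibrissae: vibrissa
  viscera: viscus
abnormal_tokens: [abnormal, abnormality]
of_token: of
morphology_label: morphology
absent_token: absent
quality_root_label: quality
quality_root_id: PATO:0000001
abnormal_label: abnormal
absence_quality_label: lacking all parts of type
absence_quality_id: PATO:0002000
unresolved_id: _UNRESOLVED_
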