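# Semantic-type allow-list for concept filtering. Edit to widen or narrow
# the categories kept from note text; everything else is discarded.
allowlist:
  - Disease or Syndrome
  - Mental or Behavioral Dysfunction
  - Injury or Poisoning
  - Sign or Symptom
  - Finding
  - Therapeutic or Preventive Procedure
  - Diagnostic Procedure
  - Laboratory Procedure
  - Pharmacologic Substance
  - Clinical Drug
  - Body Part, Organ, or Organ Component
  - Anatomical Structure
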