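# Single precisely-defined binary exposure, no SUTVA violation.
# Causes: the exposure with its causal partners U; absence of exposure with
# the preventive partners W; background mechanisms X that act regardless of
# exposure. Prevalences are illustrative defaults; override freely.
name: basic
exposures:
- name: E
  levels: [exposed, unexposed]
  reference: unexposed
components:
  U: 0.3
  W: 0.1
  X: 0.2
causes:
- when: {E: exposed}
  requires: [U]
- when: {E: unexposed}
  requires: [W]
- requires: [X]
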