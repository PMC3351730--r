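# Interference between units: the outcome depends on one's own exposure E
# and on the exposure of influential others I. U1 partners E alone, U2
# partners I alone, U3 needs both; W1 and W2 are the preventive partners of
# staying unexposed / of unexposed others; X is the background mechanism.
# Context levels are declared others_unexposed first so the canonical
# condition table reads the interference-free contrast first.
name: interference
exposures:
- name: E
  levels: [exposed, unexposed]
  reference: unexposed
- name: I
  levels: [others_unexposed, others_exposed]
  reference: others_unexposed
components:
  U1: 0.3
  U2: 0.2
  U3: 0.2
  W1: 0.05
  W2: 0.05
  X: 0.1
causes:
- requires: [X]
- when: {E: exposed}
  requires: [U1]
- when: {I: others_exposed}
  requires: [U2]
- when: {E: exposed, I: others_exposed}
  requires: [U3]
- when: {E: unexposed}
  requires: [W1]
- when: {I: others_unexposed}
  requires: [W2]
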