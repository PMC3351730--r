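# Two unrepresented versions of treatment (consistency violation): the
# nominal exposure "ride" really is flat rides or hilly rides, with distinct
# causal partners U1 and U2. W acts preventively with no ride; X is the
# background mechanism. Prevalences are illustrative defaults.
name: versions
exposures:
- name: ride
  levels: [flat, hilly, none]
  reference: none
components:
  U1: 0.5
  U2: 0.5
  W: 0.1
  X: 0.2
causes:
- when: {ride: flat}
  requires: [U1]
- when: {ride: hilly}
  requires: [U2]
- when: {ride: none}
  requires: [W]
- requires: [X]
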