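# Conventional SERCA1a segment map: transmembrane helices M1-M10 and the
# cytosolic headpiece domains (N = nucleotide, P = phosphorylation,
# A = actuator). Ranges follow the structural literature on the pump and are
# a shipped convention, overridable by the user.
M1: [49, 77]
M2: [89, 120]
M3: [246, 274]
M4: [289, 322]
M5: [740, 770]
M6: [787, 810]
M7: [828, 852]
M8: [891, 915]
M9: [929, 952]
M10: [963, 994]
A-domain:
  - [1, 48]
  - [121, 245]
N-domain: [360, 604]
P-domain:
  - [330, 359]
  - [605, 737]
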