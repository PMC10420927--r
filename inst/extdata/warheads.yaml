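aldehyde:
  smarts: '[CX3H1](=O)[#6]'
  specificity_rank: 2
alpha_haloketone:
  smarts: '[#6][CX3](=O)[CX4;H1,H2][F,Cl,Br,I]'
  specificity_rank: 2
acrylate:
  smarts: '[CX3]=[CX3][CX3](=O)[OX2][#6]'
  specificity_rank: 2
alkynyl_benzoate:
  smarts: '[CX2]#[CX2]c1ccccc1[CX3](=O)[OX2][#6]'
  specificity_rank: 1
boronic_acid:
  smarts: '[BX3]([OX2H])[OX2H]'
  specificity_rank: 2
cyanoacrylamide:
  smarts: '[NX1]#[CX2][CX3](=[CX3])[CX3](=O)[NX3]'
  specificity_rank: 1
cyanamide:
  smarts: '[NX3][CX2]#[NX1]'
  specificity_rank: 2
epoxide:
  smarts: '[CX4]1[OX2][CX4]1'
  specificity_rank: 2
reactive_ester:
  smarts: '[CX3](=O)[OX2][$(c1ccc(cc1)[N+](=O)[O-]),$(c1cccc(c1)[N+](=O)[O-]),$(c1ccccc1[N+](=O)[O-]),$(c1c(F)c(F)c(F)c(F)c1F),$([NX3]([CX3]=O)[CX3]=O)]'
  specificity_rank: 3
sulfonyl_fluoride:
  smarts: '[SX4](=O)(=O)F'
  specificity_rank: 2
terminal_alkyne:
  smarts: '[CX2]#[CX2H1]'
  specificity_rank: 3
vinyl_sulfone:
  smarts: '[CX3]=[CX3][SX4](=O)(=O)[#6]'
  specificity_rank: 2
acrylamide:
  smarts: '[CX3]=[CX3][CX3](=O)[NX3]'
  specificity_rank: 3
heterocyclic_urea:
  smarts: '[c;$(c:[n,o,s]),$(c:c:[n,o,s]),$(c:c:c:[n,o,s])][NX3][CX3](=O)[NX3]'
  specificity_rank: 2
suppression_pairs:
- - cyanoacrylamide
  - acrylamide
- - alkynyl_benzoate
  - terminal_alkyne
- - acrylate
  - reactive_ester
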