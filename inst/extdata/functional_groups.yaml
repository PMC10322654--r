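# Functional groups completed into reaction centers when any member atom
# changes. SMARTS use the subset understood by the package pattern engine.
- name: ester
  smarts: "[CX3](=O)[OX2][#6]"
- name: carboxylic_acid
  smarts: "[CX3](=O)[OX2H]"
- name: amide
  smarts: "[CX3](=O)[NX3]"
- name: carbamate
  smarts: "[NX3][CX3](=O)[OX2]"
- name: nitro
  smarts: "[N+](=O)[O-]"
- name: nitrile
  smarts: "[NX1]#[CX2]"
- name: aldehyde
  smarts: "[CX3H1]=[OX1]"
- name: ketone
  smarts: "[#6][CX3](=[OX1])[#6]"
- name: hydroxyl
  smarts: "[OX2H]"
- name: phenol
  smarts: "[OX2H][c]"
- name: primary_amine
  smarts: "[NX3H2]"
- name: ether
  smarts: "[#6][OX2D2][#6]"
- name: thiol
  smarts: "[SX2H]"
- name: sulfide
  smarts: "[#6][SX2D2][#6]"
- name: sulfonyl
  smarts: "[SX4](=[OX1])(=[OX1])"
- name: phosphate_ester
  smarts: "[PX4](=[OX1])([OX2])[OX2]"
- name: thiophosphate_ester
  smarts: "[PX4](=[SX1])([OX2])[OX2]"
- name: epoxide
  smarts: "C1OC1"
- name: halide
  smarts: "[F,Cl,Br,I]"
- name: azo
  smarts: "[NX2]=[NX2]"
- name: imine
  smarts: "[CX3]=[NX2]"
- name: alkyne
  smarts: "[CX2]#[CX2]"
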