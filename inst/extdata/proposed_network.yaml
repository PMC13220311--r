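variant: proposed
species:
- name: Lac
  measured: yes
- name: Lys
  measured: yes
- name: LacLys
  measured: yes
- name: 3DG
  measured: yes
- name: 1DG
  measured: yes
- name: G
  measured: yes
- name: DA
  measured: yes
- name: MGO
  measured: yes
- name: GO
  measured: yes
- name: CML
  measured: yes
- name: CEL
  measured: yes
- name: Int
  measured: no
- name: P1
  measured: no
- name: P10
  measured: no
- name: P2
  measured: no
- name: P3
  measured: no
- name: P4
  measured: no
- name: P5
  measured: no
- name: P6
  measured: no
- name: P7
  measured: no
- name: P8
  measured: no
- name: P9
  measured: no
steps:
- index: 1
  reactants:
  - Lac
  - Lys
  products:
  - LacLys
- index: 2
  reactants:
  - LacLys
  products:
  - 3DG
- index: 3
  reactants:
  - LacLys
  products:
  - 1DG
- index: 4
  reactants:
  - LacLys
  products:
  - G
- index: 5
  reactants:
  - LacLys
  products:
  - CML
- index: 6
  reactants:
  - LacLys
  products:
  - CEL
- index: 7
  reactants:
  - LacLys
  products:
  - GO
- index: 8
  reactants:
  - 1DG
  products:
  - DA
- index: 9
  reactants:
  - 1DG
  products:
  - MGO
- index: 10
  reactants:
  - G
  products:
  - GO
- index: 11
  reactants:
  - GO
  - Lys
  products:
  - CML
- index: 12
  reactants:
  - MGO
  - Lys
  products:
  - CEL
- index: 13
  reactants:
  - Lac
  products:
  - Int
- index: 14
  reactants:
  - Int
  products:
  - Lac
- index: 15
  reactants:
  - Lac
  products:
  - P1
- index: 16
  reactants:
  - LacLys
  products:
  - P2
- index: 17
  reactants:
  - 3DG
  products:
  - P3
- index: 18
  reactants:
  - 1DG
  products:
  - P4
- index: 19
  reactants:
  - G
  products:
  - P5
- index: 20
  reactants:
  - MGO
  products:
  - P6
- index: 21
  reactants:
  - GO
  products:
  - P7
- index: 22
  reactants:
  - CML
  products:
  - P8
- index: 23
  reactants:
  - CEL
  products:
  - P9
- index: 24
  reactants:
  - Lys
  products:
  - P10
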