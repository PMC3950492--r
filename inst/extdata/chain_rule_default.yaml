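carbon_max: 30
max_unsat: 6
s_min:
  acyl: 2
  alkyl: 2
  alkenyl: 3
spacing: 2
linkages_sn1:
- acyl
- alkyl
- alkenyl
linkages_sn2:
- acyl
- alkyl
- alkenyl
lyso_sn1: yes
lyso_sn2: yes
dilyso: yes
enforce_feasible: yes
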