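# Area-scaling worked examples: translate a 65 kJ/mol simulation-box pore
# free energy to a 10-um-radius giant vesicle (22 kJ/mol) and to a
# 1-mm-diameter black lipid membrane (6 kJ/mol), with open-pore
# probabilities.
stages:
  - pore_prob
seed: 1
pore_prob:
  dg_pore_kJmol: 65
  temperature_K: 300
  area_sim_nm2: 45
  geometries:
    - type: guv
      label: guv_r10um
      radius_nm: 10000.0
    - type: disc
      label: blm_d1mm
      diameter_nm: 1000000.0
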