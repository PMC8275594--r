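# Default layered finger model: bloodless stratum corneum and epidermis,
# four dermal sublayers differing in blood/water content, hypodermal fat
# filling the slab to the full depth (thickness omitted = terminal layer).
layers:
- name: stratum_corneum
  thickness_mm: 0.02
  v_blood: 0.0
  v_water: 0.05
  v_melanin: 0.0
  scatter_class: skin
- name: epidermis
  thickness_mm: 0.25
  v_blood: 0.0
  v_water: 0.2
  v_melanin: 0.02
  scatter_class: skin
- name: papillary_dermis
  thickness_mm: 0.1
  v_blood: 0.04
  v_water: 0.5
  v_melanin: 0.0
  scatter_class: skin
- name: upper_blood_net_dermis
  thickness_mm: 0.08
  v_blood: 0.3
  v_water: 0.6
  v_melanin: 0.0
  scatter_class: skin
- name: reticular_dermis
  thickness_mm: 0.2
  v_blood: 0.04
  v_water: 0.7
  v_melanin: 0.0
  scatter_class: skin
- name: deep_blood_net_dermis
  thickness_mm: 0.3
  v_blood: 0.1
  v_water: 0.7
  v_melanin: 0.0
  scatter_class: skin
- name: hypodermal_fat
  v_blood: 0.05
  v_water: 0.7
  v_melanin: 0.0
  scatter_class: fat
global:
  g: 0.9
  n_tissue: 1.4
  n_external: 1.0
  total_depth_mm: 13.0
  lateral_mm: 13.0
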