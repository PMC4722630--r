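# Packaged normal-size knowledge base.
# Bounds as published; units cm or mm; internal canonical unit is mm.
- spec_id: ln_short_axis
  entity_id: RID13296
  quality: short axis
  range_type: upper_bound
  high: 1
  unit: cm
- spec_id: submental_ln_short_axis
  entity_id: RID7710
  quality: short axis
  range_type: upper_bound
  high: 1.5
  unit: cm
- spec_id: spleen_height
  entity_id: RID86
  quality: height
  range_type: interval
  low: 11
  high: 15
  unit: cm
- spec_id: spleen_length
  entity_id: RID86
  quality: length
  range_type: interval
  low: 7
  high: 10
  unit: cm
- spec_id: spleen_width
  entity_id: RID86
  quality: width
  range_type: interval
  low: 4
  high: 6
  unit: cm
# Alternative single-bound spleen length statement; disabled because it
# conflicts with the interval form above (see vignette).
- spec_id: spleen_length_upper_alt
  entity_id: RID86
  quality: length
  range_type: upper_bound
  high: 15
  unit: cm
  enabled: no
- spec_id: aorta_root_diameter
  entity_id: RID580
  quality: diameter
  range_type: lower_bound
  low: 4
  unit: cm
- spec_id: kidney_craniocaudal
  entity_id: RID205
  quality: craniocaudal diameter
  range_type: interval
  low: 8
  high: 13
  unit: cm
- spec_id: gallbladder_wall_thickness
  entity_id: RID33779
  quality: thickness
  range_type: interval
  low: 0.1
  high: 0.3
  unit: cm
- spec_id: ureter_width
  entity_id: RID229
  quality: width
  range_type: interval
  low: 0.4
  high: 0.7
  unit: cm
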