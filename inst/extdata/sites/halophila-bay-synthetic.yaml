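site_name: halophila-bay-synthetic
latitude: -30.0
climate: temperate
tidal: subtidal
meadow_type: enduring
life_history: colonising
genus_label: Halophila
light_p:
- 0.76
- 0.754641
- 0.74
- 0.72
- 0.7
- 0.685359
- 0.68
- 0.685359
- 0.7
- 0.72
- 0.74
- 0.754641
reference_value: 600.0
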