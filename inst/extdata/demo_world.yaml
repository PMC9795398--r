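# Small demo world: 8 regions x 120 businesses over the built-in categories.
generate:
  n_regions: 8
  businesses_per_region: 120
  dishes_per_category: 4
  records_per_dish: 4
  seed: 7
analysis:
  seed: 7
  families: [linear, random_forest]
output: demo_out
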