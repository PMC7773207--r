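{
  "n_specimens": 17,
  "maxilla_count_min": 7,
  "maxilla_count_max": 11,
  "mandible_count_min": 9,
  "mandible_count_max": 15,
  "min_replacement_waves": 5,
  "net_gain_per_cycle": 2,
  "adult_net_gain_per_cycle": 1,
  "canine_cessation_bsl_mm": 90,
  "max_bsl_with_canine_replacement_mm": 88,
  "size_ratio_galesaurus_pct": 77,
  "size_ratio_thrinaxodon_pct": 91,
  "stage8_functional_pc": 7
}
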