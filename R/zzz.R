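utils::globalVariables(c(
  "x_position", "ymin", "ymax", "segment", "day", "estimate_mm", "se_mm",
  "color", "length_mm", "plate_id", "seedling_id"
))
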