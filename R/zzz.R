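## Column names used inside ggplot2::aes() in package code.
utils::globalVariables(c(
  "xmin", "xmax", "y", "count", "x", "value", "start", "end", "lane",
  "individual", "population", "px", "py", "prop", "component", "mid",
  "colorIndex", "chrom", "row", "col", "label", "bp"))
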