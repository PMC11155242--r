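# silence R CMD check notes for data.table non-standard evaluation
utils::globalVariables(c(
  ".", "department_id", "volume_t", "dept_chr", "traced_t", "untraced_t",
  "production_t", "traced_flag", "bim", "exporter", "importer", "key_",
  "bf_per_ton", "traced_share", "traced_bim", "share", "bim_total",
  "bim_cocoa", "department", "code", "y", "bf", "bc", "bt", "cocoa", "agro"))
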