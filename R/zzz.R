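.datatable.aware <- TRUE

## data.table NSE columns
utils::globalVariables(c(
  ".sample", "individual", "tissue", "p", "q", "pass", "reasons",
  "alt_count", "coverage", "chrom", "pos", "ref", "alt", ".SD", ".N",
  "site", "state", "ref_count", "vaf", "gene", "klass"))
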