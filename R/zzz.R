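#' @import data.table
NULL

.datatable.aware <- TRUE

utils::globalVariables(c(
  "q", "p", "neg_log10_p", "support", "odds_ratio", "dbset", "k",
  "snp", "gene", "score", "chrom", "pos", "pos_raw", "is_top_gene",
  "harmonic_score"
))
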