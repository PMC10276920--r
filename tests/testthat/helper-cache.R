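# Session-level cache shared across test files (testthat sources helpers
# once per run). Lets the null-calibration replicates computed in the
# acceptance suite feed the distributional property checks without being
# recomputed.
if (!exists("cf_cache", inherits = FALSE)) cf_cache <- new.env(parent = emptyenv())
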