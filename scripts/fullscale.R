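#!/usr/bin/env Rscript
# Optional long test: full-scale germinal-center run (250 x 200 field, 200
# seeder B cells, 72,000 mcs) checked against the reference steady-state
# statistics with a relaxed +/-25% tolerance. Expect hours of runtime.
# Usage: Rscript scripts/fullscale.R

library(testthat)
library(gcpotts)
test_dir("tests/longtests", stop_on_failure = FALSE)
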