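#!/usr/bin/env Rscript
## Run the whole pipeline end to end through run_pipeline() (independent of
## the intermediate files of scripts 01-04) and emit the cohort report
## tables and headline JSON under results/report/.

library(fetalkick)

bundle <- run_pipeline(reference_scenarios(rng_seed = 1L), seed = 1L,
                       verbose = TRUE)
print(bundle)
report(bundle, "results/report")
message("report written under results/report/")
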