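#!/usr/bin/env Rscript
## Synthesize the three per-fetus kick sequences (ground truth + frames)
## and store them as fixtures under results/fixtures/<id>/.

library(fetalkick)

seed <- 1L
scenarios <- reference_scenarios(rng_seed = seed)
dir.create("results/fixtures", recursive = TRUE, showWarnings = FALSE)

for (id in names(scenarios)) {
  sc <- scenarios[[id]]
  truth <- generate_kick_kinematics(sc)
  frames <- render_frames(truth, sc)
  write_fixture(truth, frames, file.path("results/fixtures", id))
  message(sprintf(
    "fetus %s: %d frames, contact from frame %d, true deflection %.2f mm",
    id, nrow(truth), which(truth$contact)[1] - 1L, max(truth$deflection_mm)))
}
message("fixtures written under results/fixtures/")
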