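#!/usr/bin/env Rscript
# Simulate a desk-scale genome-wide uptake screen: 2,000 genes on 384-well
# plates in triplicate, with 89 planted uptake-decreasing genes at -6
# plate-MADs (the same hit fraction, ~4.5%, as the 887/18,119 primary
# screen), negative (control siRNA) and positive (DNM2 siRNA) control wells,
# and ~2% of wells failing imaging QC. Writes the well table and the planted
# truth for the downstream drivers.

library(ldlscreen)

seed <- 20260930L
dir.create("results", showWarnings = FALSE)

hits <- setNames(rep(-6, 89),
                 sprintf("gene%05d", round(seq(2, 1995, length.out = 89))))
spec <- screen_sim_spec(n_genes = 2000L, hits = hits, seed = seed)
sim <- gen_screen(spec)

write_result_table(sim$wells, "results/screen_wells.csv",
                   config = run_config(seed = seed), seed = seed)
write_result_table(sim$truth, "results/screen_truth.csv", seed = seed)

cat(sprintf("simulated %d wells (%d plates x 3 replicates), %d planted hits\n",
            nrow(sim$wells), length(unique(sim$wells$plate_id)),
            nrow(sim$truth)))
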