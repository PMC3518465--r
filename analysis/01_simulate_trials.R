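#!/usr/bin/env Rscript

# Stage 1: simulate the study's five conditions from the packaged
# two-process race scenarios and write the trial tables.
#
# Each table holds 12 synthetic subjects x 192 trials; a small spoilage
# fraction is injected so the downstream validity filter has work to do,
# mirroring the ~2% of discarded trials a real session produces.

library(sacchoice)

seed <- 1L
out_dir <- "results/trials"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

scenarios <- packaged_scenarios(seed = seed)
for (nm in names(scenarios)) {
  spec <- scenarios[[nm]]
  spec$spoil_fraction <- 0.02
  trials <- generate_srt_data(spec)
  path <- file.path(out_dir, paste0(nm, ".tsv"))
  write_trial_table(trials, path)
  message(sprintf("%-18s %4d trials -> %s", nm, nrow(trials), path))
}
message("done; planted values travel with packaged_scenarios(), not the tables")
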