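#!/usr/bin/env Rscript
# Stage 1: generate a small demonstration cohort to disk (EDF + CSVs +
# manifest). The statistical stages (02-04) regenerate their own cohorts
# in memory at full scale; this stage exists to exercise and document the
# on-disk interchange formats.

suppressPackageStartupMessages(library(somnotherm))

out_dir <- "results/demo_cohort"
seed <- 20260929L

cohort <- generate_cohort(
  list(list(preset = make_preset("WT"), n_subjects = 2,
            ambient_blocks = data.frame(label = c("RT", "WARM"),
                                        duration_s = c(600, 600))),
       list(preset = make_preset("DS"), n_subjects = 2,
            ambient_blocks = data.frame(label = c("RT", "WARM"),
                                        duration_s = c(600, 600)))),
  seed = seed, out_dir = out_dir)

message("Wrote ", length(cohort), " sessions to ", out_dir)
for (sid in names(cohort)) {
  gt <- cohort[[sid]]$ground_truth
  message(sprintf(
    "  %s: %d epochs, %d NREM onsets (%d with temperature drop), %d spikes",
    sid, n_epochs(gt$hypnogram), length(gt$nrem_onsets_s),
    length(gt$temp_drop_onsets_s), length(gt$spike_times_s)))
}
message("Manifest: ", attr(cohort, "manifest"))

# round-trip sanity: EDF quantization error is bounded by one step
rec <- cohort[[1]]$recording
back <- read_edf(file.path(out_dir, paste0(names(cohort)[1], ".edf")))
err <- max(abs(back$channels$ECoG - rec$channels$ECoG))
message(sprintf("EDF round-trip max error: %.4f uV", err))
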