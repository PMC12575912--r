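#!/usr/bin/env Rscript
# Step 1: simulate the study inputs.
#
# Generates the default two-group, two-reader biomarker cohort (26 LVI+ /
# 47 LVI-) and a synthetic PET lesion volume, and writes them together with
# the run configuration under results/.

suppressPackageStartupMessages(library(petivimdki))

seed <- 20260924L
out <- "results"
dir.create(out, showWarnings = FALSE)

cfg <- default_cohort_config(seed = seed)
write_config(cfg, file.path(out, "config.yaml"), extra = list(snr = 50))

cohort <- generate_cohort(cfg)
write_cohort(cohort, file.path(out, "cohort.csv"))
cat(sprintf("cohort: %d subjects (%d LVI+, %d LVI-), 2 readers -> %s\n",
            length(unique(cohort$subject_id)),
            sum(cohort$lvi == "+") / 2, sum(cohort$lvi == "-") / 2,
            file.path(out, "cohort.csv")))

vol <- generate_lesion_volume(suv_peak = 6.07, background = 1, radius = 15,
                              spacing = 2, profile = "tapered",
                              noise_sd = 0.15, seed = seed)
write_pet_volume(vol, file.path(out, "lesion.nii.gz"))
cat(sprintf("lesion volume: %s voxels, SUVmax %.2f -> %s\n",
            paste(dim(vol$suv), collapse = "x"), max(vol$suv),
            file.path(out, "lesion.nii.gz")))

# noise-free and Rician-noised diffusion curves at the group medians
b <- bvalue_scheme("ivim")
curves <- sapply(1:20, function(i) {
  add_rician_noise(ivim_signal(b, 0.72e-3, 75.06e-3, 0.4156), 1, 50,
                   seed = seed + i)
})
write_curves(b, curves, file.path(out, "ivim_curves.csv"))
cat("20 noisy IVIM curves ->", file.path(out, "ivim_curves.csv"), "\n")
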