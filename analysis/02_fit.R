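#!/usr/bin/env Rscript
# Step 2: invert the diffusion models and extract PET metrics.
#
# Fits the simulated signal curves with the segmented IVIM, full IVIM, DKI
# and ADC fitters, runs the Monte-Carlo recovery study at the published
# group-median parameters, and extracts the 40%-isocontour VOI metrics of
# the simulated lesion. Writes recovery tables under results/.

suppressPackageStartupMessages(library(petivimdki))

seed <- 20260924L
out <- "results"
dir.create(out, showWarnings = FALSE)

# --- fit the stored curves ---
cur <- read_curves(file.path(out, "ivim_curves.csv"))
fits <- do.call(rbind, lapply(seq_len(ncol(cur$signals)), function(i) {
  seg <- fit_ivim_segmented(cur$b, cur$signals[, i])
  full <- fit_ivim_full(cur$b, cur$signals[, i], seg)
  data.frame(curve = i, d_seg = seg$d, dstar_seg = seg$dstar, f_seg = seg$f,
             d_full = full$d, dstar_full = full$dstar, f_full = full$f,
             rss_seg = seg$rss, rss_full = full$rss)
}))
write.csv(fits, file.path(out, "ivim_fits.csv"), row.names = FALSE)
cat(sprintf("fitted %d curves; median D (segmented) = %.4g mm2/s (truth 7.2e-04)\n",
            nrow(fits), median(fits$d_seg)))

# --- Monte-Carlo recovery at the published medians, SNR 50, 500 curves ---
protocols <- list(
  ivim_pos = list(model = "ivim", d = 0.72e-3, dstar = 75.06e-3, f = 0.4156),
  ivim_neg = list(model = "ivim", d = 0.96e-3, dstar = 68.19e-3, f = 0.410),
  dki_pos  = list(model = "dki", dapp = 2.29e-3, kapp = 0.84),
  dki_neg  = list(model = "dki", dapp = 2.69e-3, kapp = 0.70)
)
recovery <- do.call(rbind, lapply(names(protocols), function(nm) {
  p <- protocols[[nm]]
  if (p$model == "ivim") {
    b <- bvalue_scheme("ivim")
    clean <- ivim_signal(b, p$d, p$dstar, p$f)
    est <- withr::with_seed(seed, replicate(500, {
      f <- fit_ivim_segmented(b, add_rician_noise(clean, 1, 50))
      c(f$d, f$dstar, f$f)
    }))
    data.frame(protocol = nm,
               parameter = c("D", "Dstar", "f"),
               truth = c(p$d, p$dstar, p$f),
               median_fit = apply(est, 1, median),
               sd_fit = apply(est, 1, sd))
  } else {
    b <- bvalue_scheme("dki")
    clean <- dki_signal(b, p$dapp, p$kapp, validity = "none")
    est <- withr::with_seed(seed, replicate(500, {
      f <- fit_dki(b, add_rician_noise(clean, 1, 50))
      c(f$dapp, f$kapp)
    }))
    data.frame(protocol = nm,
               parameter = c("Dapp", "Kapp"),
               truth = c(p$dapp, p$kapp),
               median_fit = apply(est, 1, median),
               sd_fit = apply(est, 1, sd))
  }
}))
recovery$rel_err <- recovery$median_fit / recovery$truth - 1
write.csv(recovery, file.path(out, "recovery.csv"), row.names = FALSE)
cat("recovery study (500 curves each, SNR 50):\n")
print(recovery, digits = 3)
cat("note the D* rows: the pseudo-diffusion sd dwarfs the D sd,\n",
    "matching its known instability.\n")

# --- PET VOI metrics of the simulated lesion ---
vol <- read_pet_volume(file.path(out, "lesion.nii.gz"))
metrics <- compute_pet_metrics(extract_voi(vol, threshold_fraction = 0.4))
write.csv(metrics, file.path(out, "pet_metrics.csv"), row.names = FALSE)
cat(sprintf("lesion VOI: SUVmax %.2f, MTV %.2f cm3, TLG %.2f g (40%% isocontour)\n",
            metrics$suvmax, metrics$mtv_cm3, metrics$tlg_g))
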