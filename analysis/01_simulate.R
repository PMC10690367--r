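#!/usr/bin/env Rscript
# Simulate a demonstration DSC phantom at the reference acquisition
# (60 frames x 1.87 s, TE = 40 ms): baseline plateau, gamma-variate bolus
# per tissue class, leaky tumor block, Gaussian signal noise. Writes the 4D
# series, the masks and the ground truth, and checks the noise calibration.

suppressPackageStartupMessages(library(dscradiomics))

out_dir <- "results/phantom"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

spec <- phantom_spec(noise_sd = 1, seed = 42)
ph <- build_phantom(spec)

write_nifti_map(unclass(ph$series), file.path(out_dir, "dsc_series.nii.gz"))
write_nifti_mask(ph$brain_mask, file.path(out_dir, "brain_mask.nii.gz"))
write_nifti_mask(ph$tumor_mask, file.path(out_dir, "tumor_mask.nii.gz"))

tg <- series_time_grid(ph$series)
write_aif_csv(tg, ph$ground_truth$aif, file.path(out_dir, "aif.csv"))

truth <- do.call(rbind, lapply(ph$ground_truth$classes, function(tc) {
  data.frame(label = tc$label,
             Ft = tc$kinetics$Ft, t1 = tc$kinetics$t1,
             sigma1 = tc$kinetics$sigma1, a1 = tc$kinetics$a1,
             K1 = ifelse(is.null(tc$leakage), NA, tc$leakage$K1),
             K2 = ifelse(is.null(tc$leakage), NA, tc$leakage$K2),
             Kep = ifelse(is.null(tc$leakage), NA, tc$leakage$Kep))
}))
write.csv(truth, file.path(out_dir, "ground_truth.csv"), row.names = FALSE)

# calibration check: baseline residual SD should match the configured noise
base <- matrix(ph$series, ncol = spec$n_timepoints)[, seq_len(spec$n_baseline)]
nb <- spec$n_baseline
sd_hat <- sd(base - rowMeans(base)) * sqrt(nb / (nb - 1))
cat(sprintf("phantom grid %s, %d frames at %.2f s, TE %.0f ms\n",
            paste(spec$grid_shape, collapse = "x"), spec$n_timepoints,
            spec$dt, 1000 * spec$te))
cat(sprintf("tumor voxels: %d, brain voxels: %d\n",
            sum(ph$tumor_mask), sum(ph$brain_mask)))
cat(sprintf("baseline noise SD: configured %.3f, measured %.3f\n",
            spec$noise_sd, sd_hat))
cat("wrote series, masks, AIF and ground truth under", out_dir, "\n")
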