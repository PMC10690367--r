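#!/usr/bin/env Rscript
# Per-map IDH-status classification on the cohort feature table: inside each
# of 5 stratified folds, run the three-step selection (variance -> ANOVA ->
# L1 logistic), z-score with train statistics, balance the training fold
# with SMOTE and train an SVM-RBF; evaluate on the untouched test fold.
# Writes the per-map metrics table (mean +/- SD, the study-table layout).

suppressPackageStartupMessages(library(dscradiomics))

if (!file.exists("results/features.csv")) {
  stop("run analysis/03_extract_features.R first", call. = FALSE)
}
tab <- read_feature_csv("results/features.csv")
seed <- 42L
maps <- c("MSI", "nrCBV", "K2_unidir", "K1_bidir")

res <- per_map_cv(tab, maps = maps, k = 5, seed = seed,
                  variance_threshold = 1e-8, alpha = 0.05, C = 0.3)

fmt <- function(m, s) sprintf("%.1f ± %.1f", 100 * m, 100 * s)
rows <- lapply(maps, function(m) {
  r <- res$reports[[m]]
  data.frame(map = m,
             sensitivity = fmt(r$mean["sensitivity"], r$sd["sensitivity"]),
             specificity = fmt(r$mean["specificity"], r$sd["specificity"]),
             f1 = fmt(r$mean["f1"], r$sd["f1"]),
             acc = fmt(r$mean["acc"], r$sd["acc"]),
             auroc = fmt(r$mean["auroc"], r$sd["auroc"]))
})
metrics <- do.call(rbind, rows)
print(metrics, row.names = FALSE)
write.csv(metrics, "results/metrics_per_map.csv", row.names = FALSE)

cat(sprintf("\nbest-accuracy map: %s (ACC %.1f%%, AUROC %.1f%%)\n",
            res$best_map, 100 * res$summary[res$best_map, "acc"],
            100 * res$summary[res$best_map, "auroc"]))
sel <- table(unlist(res$reports[[res$best_map]]$selected))
cat("features selected in >= 3 folds of the best map:\n")
print(names(sel)[sel >= 3])
cat("wrote results/metrics_per_map.csv\n")
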