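#!/usr/bin/env Rscript
# Extract the five morphometric features (RA, CP, BL, BW, E) from the
# rendered mask gallery and check them against the generating shapes'
# analytic ground truth.

suppressMessages(library(pigloop))

features <- extract_features_dir("results/masks",
                                 out_csv = "results/features.csv",
                                 scale = 1 / 2)  # masks drawn at 2 px/cm
truth <- read.csv("results/mask_truth.csv")
tab <- merge(features, truth, by = "mask_id")

ra_err <- abs(tab$RA - tab$true_area_px / 512^2) / (tab$true_area_px / 512^2)
true_bl_cm <- 2 * tab$true_a_px * (1 / 2)  # px -> cm at 2 px/cm
bl_err <- abs(tab$BL - true_bl_cm) / true_bl_cm
e_err <- abs(tab$E - tab$true_ecc)
cat(sprintf("features extracted for %d masks\n", nrow(tab)))
cat(sprintf("RA vs analytic area: median rel. error %.2f%% (max %.2f%%)\n",
            median(ra_err) * 100, max(ra_err) * 100))
cat(sprintf("BL vs generating axis: median rel. error %.2f%% (max %.2f%%)\n",
            median(bl_err) * 100, max(bl_err) * 100))
cat(sprintf("E vs generating eccentricity: median abs. error %.3f\n",
            median(e_err)))
cat(sprintf("RA span of the gallery: %.3f-%.3f\n",
            min(tab$RA), max(tab$RA)))
write.csv(tab, "results/features_vs_truth.csv", row.names = FALSE)
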