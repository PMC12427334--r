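#!/usr/bin/env Rscript
# Simulate the study's raw materials: a 63-pig growth cohort with
# allometrically linked dorsal features, a small gallery of rendered
# dorsal masks with analytic ground truth, and the farm activity ledger.
# Everything downstream (02-05) reads from results/.

suppressMessages(library(pigloop))
seed <- 1L
dir.create("results/masks", showWarnings = FALSE, recursive = TRUE)

cohort <- generate_cohort(cohort_spec(n_pigs = 63, noise_sd_weight = 3,
                                      seed = seed))
write.csv(cohort, "results/cohort.csv", row.names = FALSE)
cat(sprintf("cohort: %d pigs, %d observations, true weight %.1f-%.1f kg\n",
            length(unique(cohort$pig_id)), nrow(cohort),
            min(cohort$true_weight), max(cohort$true_weight)))
adg <- attr(cohort, "adg")
cat(sprintf("per-pig ADG: mean %.3f kg/day (SD %.3f)\n",
            mean(adg), sd(adg)))

# mask gallery: one mask per pig at its median observation, with the
# generating silhouette recorded as ground truth
idx <- vapply(split(seq_len(nrow(cohort)), cohort$pig_id),
              function(i) i[ceiling(length(i) / 2)], integer(1))
sub <- cohort[idx, ]
specs <- cohort_silhouettes(sub, px_per_cm = 2, canvas = 512,
                            seed = seed + 1L)
truth <- do.call(rbind, lapply(seq_along(specs), function(i) {
  r <- render_mask(specs[[i]])
  write_mask_png(r$mask, sprintf("results/masks/%s.png", sub$pig_id[i]))
  data.frame(mask_id = sub$pig_id[i], weight_kg = sub$weight_kg[i],
             true_area_px = r$truth$area_px, true_a_px = r$truth$a,
             true_b_px = r$truth$b, true_ecc = r$truth$eccentricity)
}))
write.csv(truth, "results/mask_truth.csv", row.names = FALSE)
cat(sprintf("rendered %d dorsal masks (512x512, 2 px/cm) with ground truth\n",
            nrow(truth)))

ledger <- generate_ledger(cohort)
write_ledger(ledger, "results/ledger")
cat(sprintf("ledger: %.1f t feed, %.0f kg live weight out, %.1f kg N managed\n",
            sum(ledger$feed$tonnes), ledger$total_live_weight_kg,
            sum(ledger$manure$n_excreted_kg)))
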