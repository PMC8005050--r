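#!/usr/bin/env Rscript
# Compare the two devices' predictabilities with a paired t-test on the
# per-category leave-one-out accuracies of each giraffe (categories analyzed
# on both devices). Reads the tables written by 02, writes results/.

suppressPackageStartupMessages(library(ethoacc))

loo <- read.csv("results/individual_loo_metrics.csv")
loo <- loo[loo$category != "overall", ]
devices <- unique(loo$device)
stopifnot(length(devices) == 2)

rows <- list()
for (ind in unique(loo$individual)) {
  a1 <- loo[loo$individual == ind & loo$device == devices[1], ]
  a2 <- loo[loo$individual == ind & loo$device == devices[2], ]
  acc1 <- setNames(a1$accuracy, a1$category)
  acc2 <- setNames(a2$accuracy, a2$category)
  shared <- intersect(names(acc1), names(acc2))
  if (length(shared) < 2) next
  cmp <- paired_device_comparison(acc1[shared], acc2[shared])
  cat(sprintf("%s: %d shared categories, t = %.3g (df = %d), two-sided p = %.3g, mean accuracy difference %+.4f\n",
              ind, length(shared), cmp$t, cmp$df, cmp$p_two_sided,
              cmp$mean_difference))
  rows[[length(rows) + 1]] <- data.frame(
    individual = ind, n_categories = length(shared), t = cmp$t,
    df = cmp$df, p_two_sided = cmp$p_two_sided,
    p_one_sided_greater = cmp$p_one_sided_greater,
    mean_difference = cmp$mean_difference)
}
out <- do.call(rbind, rows)
write.csv(out, "results/device_comparison.csv", row.names = FALSE)
cat("wrote results/device_comparison.csv\n")
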