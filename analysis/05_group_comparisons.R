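#!/usr/bin/env Rscript
# Compares mean z-scores across groups with the random-intercept mixed
# model (dog as a random factor) and Tukey-adjusted pairwise
# contrasts, for the body-condition cohort and the feeding-trial
# cohort.

suppressPackageStartupMessages(library(pupgrowth))

for (name in c("body_condition", "feeding")) {
  clean <- read.csv(sprintf("results/clean_%s.csv", name),
                    stringsAsFactors = FALSE)
  cmp <- suppressWarnings(mixed_model_compare(clean, "group"))
  write.csv(cmp$contrasts,
            sprintf("results/mixed_model_contrasts_%s.csv", name),
            row.names = FALSE)
  message(name, sprintf(
    " (sigma_u = %.2f, sigma_e = %.2f):", cmp$variance$sigma_u,
    cmp$variance$sigma_e))
  ct <- cmp$contrasts
  for (i in seq_len(nrow(ct))) {
    message(sprintf(
      "  %-45s %+.2f z  [%.2f, %.2f]  p_adj %.3g", ct$contrast[i],
      ct$estimate[i], ct$lower[i], ct$upper[i], ct$p_adj[i]))
  }
}
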