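#!/usr/bin/env Rscript
# Builds the synthetic study materials: a full set of growth standards
# (2 sexes x 5 size classes) and three cohorts mirroring the validation
# datasets' structure -- a healthy clinic cohort with measurement-error
# contamination, a mixed body-condition cohort (healthy / overweight /
# obese / underweight), and a small feeding-trial cohort on three
# planes of nutrition. Writes everything under results/ as CSV.

suppressPackageStartupMessages(library(pupgrowth))

seed <- 20200923
dir.create("results", showWarnings = FALSE)

standards <- make_standard_set(seed = 11)
write_standards(standards, "results/standards.csv")
message("wrote ", length(standards), " growth standards")

profiles <- default_profiles()

## healthy clinic cohort with 2% injected weighing errors
healthy <- simulate_cohort(standards["male.III"], profiles,
                           c(healthy = 1), n_dogs = 1000, seed = seed)
contaminated <- inject_outliers(healthy$records, rate = 0.02,
                                kinds = c("double", "half",
                                          "decimal_shift"),
                                seed = seed + 1)
write.csv(contaminated$records, "results/cohort_healthy.csv",
          row.names = FALSE)
write.csv(contaminated$truth, "results/cohort_healthy_outlier_truth.csv",
          row.names = FALSE)
write.csv(healthy$truth, "results/cohort_healthy_truth.csv",
          row.names = FALSE)
message("healthy cohort: ", nrow(contaminated$records), " records, ",
        nrow(contaminated$truth), " injected outliers")

## body-condition cohort over all standards
bc <- simulate_cohort(standards, profiles,
                      c(healthy = 0.4, overweight = 0.25, obese = 0.15,
                        underweight = 0.2),
                      n_dogs = 1200, seed = seed + 2)
write.csv(bc$records, "results/cohort_body_condition.csv",
          row.names = FALSE)
write.csv(bc$truth, "results/cohort_body_condition_truth.csv",
          row.names = FALSE)
message("body-condition cohort: ", nrow(bc$records), " records from ",
        length(unique(bc$records$dog_id)), " dogs")

## feeding-trial cohort: 118% / 100% / 88% planes of nutrition
feeding <- simulate_cohort(
  standards["female.V"], profiles,
  c(feeding_supplemental = 1/3, feeding_optimal = 1/3,
    feeding_restricted = 1/3),
  n_dogs = 120, seed = seed + 3)
write.csv(feeding$records, "results/cohort_feeding.csv",
          row.names = FALSE)
write.csv(feeding$truth, "results/cohort_feeding_truth.csv",
          row.names = FALSE)
message("feeding cohort: ", nrow(feeding$records), " records")
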