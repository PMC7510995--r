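test_that("eligibility filter enforces visit counts, windows and spans", {
  r1 <- dog_records("a", c(0.25, 0.30, 0.40, 0.55), c(5, 6, 7, 8))
  e1 <- eligibility_filter(r1, "clinic")
  expect_equal(nrow(e1$exclusions), 0)

  r2 <- dog_records("b", c(0.3, 0.5, 0.8), c(5, 6, 7))
  e2 <- eligibility_filter(r2, "clinic")
  expect_equal(e2$exclusions$reason, "too_few_visits")

  # four visits crammed into under 3 months
  r3 <- dog_records("c", c(0.30, 0.35, 0.40, 0.45), c(5, 5, 6, 6))
  e3 <- eligibility_filter(r3, "clinic")
  expect_equal(e3$exclusions$reason, "span_too_short")

  # single record: colony yes, clinic no
  r4 <- dog_records("d", 1.0, 10)
  expect_equal(nrow(eligibility_filter(r4, "colony")$exclusions), 0)
  expect_equal(eligibility_filter(r4, "clinic")$exclusions$reason,
               "too_few_visits")

  # records outside the clinic window do not count
  r5 <- dog_records("e", c(0.1, 0.15, 0.5, 0.8, 1.2, 1.8, 2.2),
                    c(2, 3, 6, 7, 8, 10, 12))
  e5 <- eligibility_filter(r5, "clinic")
  expect_equal(nrow(e5$exclusions), 0)  # 4 in-window visits, span ok

  empty <- eligibility_filter(r4[0, ], "clinic")
  expect_equal(nrow(empty$eligible), 0)
})

test_that("binned box-whisker statistics match a hand computation", {
  # one bin holding {1,2,3,4,100}: type-7 quartiles Q1=2, Q3=4,
  # IQR=2, upper fence 7 so the whisker stops at 4; lower fence -1
  # so the lower whisker reaches 1
  bb <- binned_boxwhisker(rep(0.5, 5), c(1, 2, 3, 4, 100), n_bins = 1,
                          age_range = c(0, 1))
  expect_equal(bb$median_w, 3)
  expect_equal(bb$upper_whisker_len, 1)   # 4 - 3
  expect_equal(bb$lower_whisker_len, 2)   # 3 - 1
  expect_false(bb$low_support)

  # identical weights give zero-length whiskers
  bb2 <- binned_boxwhisker(runif(20, 0, 1), rep(7, 20), n_bins = 1,
                           age_range = c(0, 1))
  expect_equal(bb2$upper_whisker_len, 0)
  expect_equal(bb2$lower_whisker_len, 0)

  # 40 equal-width bins over the default range
  bb3 <- binned_boxwhisker(runif(200, 0.2, 2.25), runif(200, 5, 6))
  expect_equal(nrow(bb3), 40)
  expect_equal(diff(bb3$age_mid)[1], 2.05 / 40, tolerance = 1e-12)

  expect_error(binned_boxwhisker(1, 1, age_range = c(1, 1)), "empty")
})

test_that("smoothed bounds reproduce linear structure and contract single corrupt bins", {
  set.seed(1)
  age <- runif(4000, 0.2, 2.25)
  weight <- 4 + 10 * age + runif(4000, -1, 1)  # linear growth, flat noise
  bb <- binned_boxwhisker(age, weight)
  sb <- smooth_outlier_bounds(bb)
  use <- !is.na(sb$smoothed_median)
  fit <- lm(sb$smoothed_median[use] ~ sb$age_mid[use])
  expect_lt(max(abs(resid(fit))), 0.15)
  expect_true(all(sb$smoothed_upper_bound[use] >=
                    sb$smoothed_lower_bound[use]))

  # a corrupted bin median is shrunk towards its neighbours
  bb_bad <- bb
  k <- 20
  raw_dev <- 15
  bb_bad$median_w[k] <- bb_bad$median_w[k] + raw_dev
  sb_bad <- smooth_outlier_bounds(bb_bad)
  expect_lt(abs(sb_bad$smoothed_median[k] - sb$smoothed_median[k]), raw_dev)

  few <- binned_boxwhisker(runif(3, 0.4, 0.6), c(5, 6, 7), n_bins = 40)
  expect_error(smooth_outlier_bounds(few), "4 usable")
})

test_that("population outlier flags use strict inequalities and recover contamination", {
  set.seed(2)
  age <- runif(3000, 0.2, 2.25)
  weight <- 4 + 10 * age + rnorm(3000, 0, 0.5)
  bb <- smooth_outlier_bounds(binned_boxwhisker(age, weight))

  recs <- tibble::tibble(age_years = c(1, 1), weight_kg = c(14, 14))
  fl <- flag_population_outliers(recs, bb)
  # exactly on the bound is kept
  on_bound <- tibble::tibble(age_years = 1, weight_kg = fl$upper_bound[1])
  expect_false(flag_population_outliers(on_bound, bb)$outlier)
  just_over <- tibble::tibble(age_years = 1,
                              weight_kg = fl$upper_bound[1] + 1e-9)
  expect_true(flag_population_outliers(just_over, bb)$outlier)

  # a 10x weight at mid-age is flagged
  big <- tibble::tibble(age_years = 1.2, weight_kg = 10 * (4 + 10 * 1.2))
  expect_true(flag_population_outliers(big, bb)$outlier)

  empty <- flag_population_outliers(recs[0, ], bb)
  expect_equal(nrow(empty), 0)
})

test_that("individual gross-outlier rule flags jumps but not smooth drift", {
  # constant trajectory with one excursion to z = 3
  z <- c(0, 0, 0, 3, 0, 0)
  fl <- flag_individual_gross_outliers(z)
  expect_equal(which(fl$outlier), 4)

  # smooth drift 0 -> +1 over 20 visits: per-visit deviations tiny
  drift <- seq(0, 1, length.out = 20)
  expect_false(any(flag_individual_gross_outliers(drift)$outlier))

  # too short for context
  expect_false(any(flag_individual_gross_outliers(c(0, 5))$outlier))
})

test_that("extreme-trajectory rule is an 'entirely beyond' quantifier", {
  ch <- centile_chart()
  expect_equal(exclude_extreme_trajectories(c(3, 3.2, 4), ch),
               "trajectory_above_99.6")
  expect_equal(exclude_extreme_trajectories(c(-3, -3.5), ch),
               "trajectory_below_0.4")
  # one visit inside the chart rescues the dog
  expect_equal(exclude_extreme_trajectories(c(3.0, 2.0), ch), "eligible")
  expect_equal(exclude_extreme_trajectories(c(0, 0.5), ch), "eligible")
})

test_that("clean_dataset keeps nearly all of an uncontaminated cohort", {
  std <- make_standard_set(seed = 11)["male.III"]
  coh <- simulate_cohort(std, default_profiles(), c(healthy = 1),
                         n_dogs = 300, seed = 8)
  res <- clean_dataset(coh$records, std, mode = "clinic")
  kept_frac <- res$report$counts$n_records_kept /
    res$report$counts$n_records_in
  expect_gte(kept_frac, 0.98)
})

test_that("a misassigned small dog labelled class V is excluded below the 0.4% centile", {
  stds <- make_standard_set(seed = 11)
  small <- stds[["male.I"]]
  big <- stds[["male.V"]]
  sim <- simulate_trajectory(small, default_profiles()$healthy,
                             "mislabel", seed = 4)
  recs <- sim$records
  recs$size_class <- "V"  # wrong chart for a small dog
  res <- suppressWarnings(clean_dataset(recs, list(male.V = big),
                                        mode = "clinic"))
  expect_equal(res$report$dog_exclusions$reason, "trajectory_below_0.4")
  expect_equal(nrow(res$clean), 0)
})

test_that("empty cohorts clean to empty output without error", {
  res <- clean_dataset(dog_records("x", 1, 5)[0, ],
                       make_standard_set()["male.III"])
  expect_equal(nrow(res$clean), 0)
  expect_equal(res$report$counts$n_records_in, 0)
})

test_that("cleaning conserves records, ignores input order, and is idempotent for fixed bounds", {
  std <- make_standard_set(seed = 11)["male.III"]
  coh <- simulate_cohort(std, default_profiles(), c(healthy = 1),
                         n_dogs = 150, seed = 9)
  cont <- inject_outliers(coh$records, rate = 0.05,
                          kinds = c("double", "half"), seed = 10)
  res <- clean_dataset(cont$records, std, mode = "clinic")
  counts <- res$report$counts
  expect_equal(counts$n_records_kept + counts$n_population_outliers +
                 counts$n_individual_outliers +
                 counts$n_records_of_excluded_dogs,
               counts$n_records_in)
  # every input record appears exactly once in the flags
  expect_equal(sort(res$report$record_flags$record_id),
               seq_len(nrow(cont$records)))

  # shuffling the record order changes no flag
  set.seed(11)
  perm <- sample.int(nrow(cont$records))
  res2 <- clean_dataset(cont$records[perm, ], std, mode = "clinic")
  f1 <- res$report$record_flags$status
  f2 <- res2$report$record_flags$status[order(perm)]
  expect_equal(f2, f1)

  # with the bounds that did the flagging, kept records stay kept
  orig_bb <- smooth_outlier_bounds(binned_boxwhisker(
    cont$records$age_years, cont$records$weight_kg))
  expect_false(any(flag_population_outliers(res$clean, orig_bb)$outlier))
})
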