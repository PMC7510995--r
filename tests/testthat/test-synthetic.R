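test_that("synthetic standards respect class bounds, monotone medians and determinism", {
  s1 <- make_reference_standard("I", "male")
  expect_lt(max(s1$M), 6.5)
  expect_true(all(diff(s1$M) >= 0))
  expect_equal(length(s1$age_grid), 41)
  expect_equal(range(s1$age_grid), c(0.20, 2.25))
  # ~99% of adult weight by age 2
  m2 <- interpolate_lms(s1, 2)$M
  expect_equal(m2 / 5, 0.99, tolerance = 0.001)

  a <- make_reference_standard("III", "female", seed = 5)
  b <- make_reference_standard("III", "female", seed = 5)
  expect_identical(a, b)

  expect_error(make_reference_standard("I", adult_weight = 8),
               "outside class")
})

test_that("noise-free trajectories sit exactly on their latent z", {
  std <- test_standard()
  quiet <- sim_profile("quiet", start_z_sd = 0.5, visit_noise_sd = 0)
  sim <- simulate_trajectory(std, quiet, "q1", seed = 21)
  z <- weight_to_z(std, sim$records$age_years, sim$records$weight_kg)
  expect_equal(z, rep(sim$truth$start_z, nrow(sim$records)),
               tolerance = 1e-9)

  # noise-free drift: crossings equal the lines inside (start, start+delta)
  ch <- centile_chart()
  drift <- sim_profile("drift", start_z_sd = 0.3, visit_noise_sd = 0,
                       drift = "linear", delta_z = 1.33,
                       n_visits_range = c(8, 8))
  sim2 <- simulate_trajectory(std, drift, "q2", seed = 22)
  z2 <- weight_to_z(std, sim2$records$age_years, sim2$records$weight_kg)
  cs <- crossing_summary(z2, ch)
  z_end <- max(z2)
  expect_equal(cs$up, sum(ch$z_lines > z2[1] & ch$z_lines < z_end))
  expect_equal(cs$down, 0)
})

test_that("visit schedules satisfy the profile's window and count", {
  std <- test_standard()
  p <- sim_profile("p", n_visits_range = c(4, 4),
                   age_window = c(0.25, 2.0))
  for (s in 1:20) {
    r <- simulate_trajectory(std, p, "d", seed = s)$records
    expect_equal(nrow(r), 4)
    expect_true(all(r$age_years >= 0.25 & r$age_years <= 2.0))
    expect_true(all(diff(r$age_years) >= 0))
  }
})

test_that("cohorts follow the requested mix and are seed-reproducible", {
  std <- make_standard_set(seed = 11)
  profs <- default_profiles()
  coh <- simulate_cohort(std, profs, c(healthy = 1), n_dogs = 100,
                         seed = 30)
  expect_equal(length(unique(coh$records$dog_id)), 100)
  expect_true(all(coh$records$group == "healthy"))

  # 50/50 mix: group counts inside a 99% binomial interval of 500
  coh2 <- simulate_cohort(std, profs,
                          c(healthy = 0.5, overweight = 0.5),
                          n_dogs = 1000, seed = 31)
  n_h <- sum(coh2$truth$profile == "healthy")
  expect_true(abs(n_h - 500) < qnorm(0.995) * sqrt(1000 * 0.25) + 1)

  # different seeds change weights, not schema
  c1 <- simulate_cohort(std, profs, c(healthy = 1), 20, seed = 1)
  c2 <- simulate_cohort(std, profs, c(healthy = 1), 20, seed = 2)
  expect_identical(names(c1$records), names(c2$records))
  expect_false(identical(c1$records$weight_kg, c2$records$weight_kg))
  # same seed reproduces exactly
  c3 <- simulate_cohort(std, profs, c(healthy = 1), 20, seed = 1)
  expect_identical(c1$records, c3$records)

  expect_error(simulate_cohort(std, profs, c(healthy = 1), 0, seed = 1),
               "at least 1")
  expect_error(simulate_cohort(std, profs, c(healthy = 0.6), 5, seed = 1),
               "sum to 1")
})

test_that("growing a cohort never reshuffles existing dogs", {
  std <- make_standard_set(seed = 11)
  profs <- default_profiles()
  small <- simulate_cohort(std, profs, c(healthy = 1), 25, seed = 7)
  big <- simulate_cohort(std, profs, c(healthy = 1), 60, seed = 7)
  first25 <- big$records[big$records$dog_id %in%
                           unique(small$records$dog_id), ]
  expect_equal(as.data.frame(first25), as.data.frame(small$records))
})

test_that("outlier injection is truthful and rate-controlled", {
  std <- make_standard_set(seed = 11)["male.III"]
  coh <- simulate_cohort(std, default_profiles(), c(healthy = 1),
                         n_dogs = 600, seed = 40)

  zero <- inject_outliers(coh$records, rate = 0, seed = 41)
  expect_identical(zero$records, coh$records)
  expect_equal(nrow(zero$truth), 0)

  cont <- inject_outliers(coh$records, rate = 0.02, seed = 42)
  n_rec <- nrow(coh$records)
  expect_true(abs(nrow(cont$truth) - 0.02 * n_rec) <
                qnorm(0.995) * sqrt(n_rec * 0.02 * 0.98) + 1)
  # every truth-flagged record really changed
  expect_true(all(cont$records$weight_kg[cont$truth$row] !=
                    cont$truth$original_weight))
  # unflagged records are untouched
  untouched <- setdiff(seq_len(n_rec), cont$truth$row)
  expect_identical(cont$records$weight_kg[untouched],
                   coh$records$weight_kg[untouched])
})

test_that("a noiseless drift-free cohort passes the trajectory-level stages untouched", {
  std <- make_standard_set(seed = 11)["male.IV"]
  silent <- sim_profile("silent", start_z_sd = 0.8, visit_noise_sd = 0)
  coh <- simulate_cohort(std, list(silent = silent), c(silent = 1),
                         n_dogs = 300, seed = 50)
  res <- clean_dataset(coh$records, std, mode = "clinic")
  # constant trajectories trigger no individual-level rule; the
  # population stage and the outermost-centile rule may still trim the
  # extreme tail of the start distribution (dogs genuinely sitting
  # beyond the 0.4/99.6 lines are excluded by definition)
  expect_equal(res$report$counts$n_individual_outliers, 0)
  excl <- res$report$dog_exclusions
  expect_true(all(excl$reason %in% c("trajectory_above_99.6",
                                     "trajectory_below_0.4",
                                     "no_kept_records")))
  expect_lte(nrow(excl), 0.02 * 300)
  expect_gte(res$report$counts$n_records_kept /
               res$report$counts$n_records_in, 0.98)
  cr <- cohort_crossings(res$clean, centile_chart(), group_col = "group")
  expect_true(all(cr$total[cr$scorable] == 0))
})

test_that("no-drift cohorts have normal z-scores at fixed age", {
  std <- make_standard_set(seed = 11)["female.II"]
  p <- sim_profile("h", start_z_sd = 1, visit_noise_sd = 0.25,
                   n_visits_range = c(6, 6))
  coh <- simulate_cohort(std, list(h = p), c(h = 1), n_dogs = 400,
                         seed = 60)
  s <- std[[1]]
  z <- weight_to_z(s, coh$records$age_years, coh$records$weight_kg)
  # first visit per dog: independent draws, sd ~ sqrt(1 + 0.25^2)
  first <- !duplicated(coh$records$dog_id)
  expect_gt(stats::shapiro.test(z[first])$p.value, 0.01)
  expect_equal(sd(z[first]), sqrt(1 + 0.25^2), tolerance = 0.1)
})
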