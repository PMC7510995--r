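CLASS_BOUNDS <- list(I = c(0, 6.5), II = c(6.5, 9), III = c(9, 15),
                     IV = c(15, 30), V = c(30, 40))

## counter-based per-unit seed: cohort size changes never reshuffle
## already-generated dogs
substream_seed <- function(seed, index) {
  (as.integer(seed) + 7919L * as.integer(index)) %% .Machine$integer.max
}

#' Build a synthetic growth standard
#'
#' Constructs an age-gridded LMS standard with a Gompertz median curve
#' `M(age) = A * exp(-b * exp(-k * age))` reaching about 99 percent of
#' adult weight `A` by age 2, a coefficient of variation decreasing
#' from about 0.18 in early growth to about 0.10 in adulthood, and a
#' constant Box-Cox power (default -0.2, mild right skew typical of
#' bodyweight). Gridded at `n_grid` ages over [0.20, 2.25] years.
#' Deterministic given its parameters; a `seed` perturbs the shape
#' parameters slightly so a set of standards is not perfectly
#' congruent across classes.
#'
#' @param size_class `"I"`..`"V"`; adult weight must fall inside the
#'   class boundaries.
#' @param sex `"male"` or `"female"`.
#' @param adult_weight Adult weight `A` in kg; defaults to a
#'   mid-class value.
#' @param k Gompertz rate per year; defaults decrease with size class
#'   (small breeds mature earlier).
#' @param L Constant Box-Cox power (default -0.2).
#' @param s_early,s_adult Coefficient of variation at the grid start
#'   and its adult asymptote.
#' @param n_grid Number of grid ages (default 41).
#' @param age_range Grid range in years (default `c(0.20, 2.25)`).
#' @param seed Optional integer; perturbs `k` and `s_early` by a few
#'   percent, reproducibly.
#' @return A [growth_standard()].
#' @export
make_reference_standard <- function(size_class, sex = "male",
                                    adult_weight = NULL, k = NULL,
                                    L = -0.2, s_early = 0.18,
                                    s_adult = 0.10, n_grid = 41,
                                    age_range = c(0.20, 2.25),
                                    seed = NULL) {
  size_class <- match.arg(size_class, names(CLASS_BOUNDS))
  defaults_A <- c(I = 5, II = 7.7, III = 12, IV = 22, V = 34)
  defaults_k <- c(I = 3.4, II = 3.2, III = 3.0, IV = 2.6, V = 2.3)
  if (is.null(adult_weight)) adult_weight <- defaults_A[[size_class]]
  if (is.null(k)) k <- defaults_k[[size_class]]
  bounds <- CLASS_BOUNDS[[size_class]]
  if (adult_weight < bounds[1] || adult_weight >= bounds[2]) {
    stop(sprintf("adult weight %.1f kg outside class %s bounds [%g, %g)",
                 adult_weight, size_class, bounds[1], bounds[2]))
  }
  if (!is.null(seed)) {
    set.seed(substream_seed(seed, match(size_class, names(CLASS_BOUNDS)) +
                              5L * (sex == "female")))
    k <- k * runif(1, 0.95, 1.05)
    s_early <- s_early * runif(1, 0.95, 1.05)
  }
  b <- -log(0.99) * exp(2 * k)  # M(2) = 0.99 * A
  age <- seq(age_range[1], age_range[2], length.out = n_grid)
  M <- adult_weight * exp(-b * exp(-k * age))
  S <- s_adult + (s_early - s_adult) * exp(-1.5 * (age - age_range[1]))
  growth_standard(sex, size_class, age, L = rep(L, n_grid), M = M, S = S)
}

#' A full set of synthetic standards
#'
#' One standard per sex and size class (10 in all); female adult
#' weights are 90 percent of the male value for the class.
#'
#' @param seed Optional integer, see [make_reference_standard()].
#' @return Named list keyed `"<sex>.<size_class>"`.
#' @export
make_standard_set <- function(seed = NULL) {
  out <- list()
  for (sx in c("male", "female")) {
    for (cl in names(CLASS_BOUNDS)) {
      A <- c(I = 5, II = 7.7, III = 12, IV = 22, V = 34)[[cl]]
      if (sx == "female") A <- A * 0.9
      out[[std_key(sx, cl)]] <- make_reference_standard(
        cl, sx, adult_weight = A, seed = seed)
    }
  }
  out
}

#' Define a simulation profile
#'
#' A profile describes one growth pattern on the z-score scale:
#' where trajectories start (between-dog distribution), how their
#' latent z drifts with age, and how noisy and autocorrelated the
#' visit-to-visit measurements are. Because drifts are expressed in z,
#' profiles are size-class invariant (one chart channel is about 2/3
#' of a z-score on the nine-centile chart).
#'
#' @param name Profile name (also the emitted group label unless
#'   overridden).
#' @param start_z_mean,start_z_sd Between-dog starting z distribution.
#' @param drift `"none"`, `"linear"` (linear in age) or
#'   `"saturating"` (exponential approach); scaled so the latent z
#'   displacement at age 2 equals `delta_z`.
#' @param delta_z Terminal z displacement at age 2.
#' @param visit_noise_sd Within-dog visit noise, z units (default
#'   0.25).
#' @param visit_autocorr AR(1) coefficient of the visit noise in
#'   [0, 1) (default 0.6).
#' @param n_visits_range Integer range of visits per dog.
#' @param age_window Ages visits fall in (years).
#' @param contamination_rate Fraction of records perturbed when
#'   [inject_outliers()] is asked to use the profile's own rate.
#' @param group_label Group label written on the records.
#' @return An object of class `sim_profile`.
#' @export
sim_profile <- function(name, start_z_mean = 0, start_z_sd = 1,
                        drift = c("none", "linear", "saturating"),
                        delta_z = 0, visit_noise_sd = 0.25,
                        visit_autocorr = 0.6, n_visits_range = c(4, 12),
                        age_window = c(0.25, 2.0),
                        contamination_rate = 0, group_label = name) {
  drift <- match.arg(drift)
  stopifnot(visit_noise_sd >= 0, abs(visit_autocorr) < 1,
            age_window[1] < age_window[2],
            n_visits_range[1] >= 1,
            n_visits_range[1] <= n_visits_range[2],
            contamination_rate >= 0, contamination_rate <= 0.2)
  structure(list(name = name, start_z_mean = start_z_mean,
                 start_z_sd = start_z_sd, drift = drift,
                 delta_z = delta_z, visit_noise_sd = visit_noise_sd,
                 visit_autocorr = visit_autocorr,
                 n_visits_range = as.integer(n_visits_range),
                 age_window = age_window,
                 contamination_rate = contamination_rate,
                 group_label = group_label),
            class = "sim_profile")
}

#' Built-in simulation profiles
#'
#' Presets mirroring the growth patterns the validation analyses look
#' for: centile-tracking healthy dogs; upward drifts for dogs becoming
#' overweight (terminal +1.4 z) or obese (+2.2 z); a downward drift
#' for underweight (-1.2 z); low-start disease profiles
#' (retarded growth: start -0.8 z with a shallow saturating fall;
#' nutritional osteodystrophy: start -1.4 z falling a further 1.0 z);
#' a mild accelerated-growth profile; and feeding planes at 118, 100
#' and 88 percent of optimal energy intake mapped to terminal drifts
#' of +1.3, 0 and -0.7 z over a first-year window.
#'
#' @return Named list of [sim_profile()] objects.
#' @export
default_profiles <- function() {
  feed_win <- c(0.20, 1.0)
  list(
    healthy = sim_profile("healthy"),
    overweight = sim_profile("overweight", drift = "linear",
                             delta_z = 1.4),
    obese = sim_profile("obese", drift = "linear", delta_z = 2.2),
    underweight = sim_profile("underweight", drift = "linear",
                              delta_z = -1.2),
    retarded_growth = sim_profile("retarded_growth", start_z_mean = -0.8,
                                  drift = "saturating", delta_z = -0.3),
    nutritional_osteodystrophy = sim_profile(
      "nutritional_osteodystrophy", start_z_mean = -1.4,
      drift = "linear", delta_z = -1.0),
    accelerated_growth = sim_profile("accelerated_growth",
                                     start_z_mean = 0.4,
                                     drift = "saturating", delta_z = 0.5),
    feeding_supplemental = sim_profile("feeding_supplemental",
                                       drift = "linear", delta_z = 1.3,
                                       age_window = feed_win),
    feeding_optimal = sim_profile("feeding_optimal",
                                  age_window = feed_win),
    feeding_restricted = sim_profile("feeding_restricted",
                                     drift = "linear", delta_z = -0.7,
                                     age_window = feed_win))
}

drift_at <- function(profile, age) {
  a0 <- profile$age_window[1]
  span <- 2.0 - a0
  switch(profile$drift,
         none = rep(0, length(age)),
         linear = profile$delta_z * (age - a0) / span,
         saturating = profile$delta_z *
           (1 - exp(-3 * (age - a0))) / (1 - exp(-3 * span)))
}

#' Simulate one dog's trajectory
#'
#' Draws a starting z from the profile's between-dog distribution,
#' visit ages as an even grid over the age window with uniform jitter,
#' a stationary AR(1) visit-noise series, composes latent
#' `z = start + drift(age) + noise`, and converts to weights through
#' the standard's inverse LMS transform.
#'
#' @param std A [growth_standard()].
#' @param profile A [sim_profile()].
#' @param dog_id Identifier written on the records.
#' @param seed Integer seed (required for reproducibility).
#' @return List with `records` (tibble of weight records) and `truth`
#'   (one-row tibble: `dog_id`, `profile`, `start_z`,
#'   `terminal_drift_z`).
#' @export
simulate_trajectory <- function(std, profile, dog_id, seed) {
  set.seed(seed)
  n <- if (profile$n_visits_range[1] == profile$n_visits_range[2])
    profile$n_visits_range[1] else
      sample(profile$n_visits_range[1]:profile$n_visits_range[2], 1)
  win <- profile$age_window
  grid <- seq(win[1], win[2], length.out = n)
  gap <- if (n > 1) diff(grid)[1] else diff(win)
  ages <- sort(pmin(pmax(grid + runif(n, -0.4, 0.4) * gap, win[1]),
                    win[2]))
  start_z <- rnorm(1, profile$start_z_mean, profile$start_z_sd)
  rho <- profile$visit_autocorr
  sdv <- profile$visit_noise_sd
  e <- numeric(n)
  if (sdv > 0) {
    e[1] <- rnorm(1, 0, sdv)
    if (n > 1) {
      for (j in 2:n) e[j] <- rho * e[j - 1] + rnorm(1, 0, sdv * sqrt(1 - rho^2))
    }
  }
  z <- start_z + drift_at(profile, ages) + e
  weight <- rep(NA_real_, n)
  for (j in seq_len(n)) {
    w <- tryCatch(z_to_weight(std, ages[j], z[j]), error = function(e) NA)
    tries <- 0
    while (is.na(w) && tries < 20) {
      z[j] <- start_z + drift_at(profile, ages[j]) + rnorm(1, 0, max(sdv, 0.1))
      w <- tryCatch(z_to_weight(std, ages[j], z[j]), error = function(e) NA)
      tries <- tries + 1
    }
    if (is.na(w)) stop("latent z persistently outside the invertible LMS domain")
    weight[j] <- w
  }
  records <- tibble::tibble(
    dog_id = dog_id, sex = std$sex, breed = "synthetic",
    mixed_breed = FALSE, size_class = std$size_class,
    adult_weight_kg = NA_real_, age_years = ages, weight_kg = weight,
    visit_type = NA_character_, bcs_label = NA_character_,
    diagnosis = NA_character_, group = profile$group_label)
  profile_name <- profile$name
  delta_z <- profile$delta_z
  truth <- tibble::tibble(dog_id = dog_id, profile = profile_name,
                          start_z = start_z,
                          terminal_drift_z = delta_z)
  list(records = records, truth = truth)
}

#' Simulate a longitudinal cohort
#'
#' Assigns each dog a profile at random according to `mix` and a
#' standard at random from `standards`, then simulates all
#' trajectories with per-dog substreams derived from the global seed
#' (so enlarging the cohort never reshuffles existing dogs).
#'
#' @param standards Named list of standards (as from
#'   [make_standard_set()]); dogs are assigned uniformly at random.
#' @param profiles Named list of [sim_profile()] objects.
#' @param mix Named proportions over `names(profiles)`, summing to 1.
#' @param n_dogs Number of dogs (>= 1).
#' @param seed Integer seed.
#' @return List with `records` (tibble) and `truth` (tibble:
#'   `dog_id`, `profile`, `sex`, `size_class`, `start_z`,
#'   `terminal_drift_z`).
#' @export
simulate_cohort <- function(standards, profiles, mix, n_dogs, seed) {
  if (n_dogs < 1) stop("n_dogs must be at least 1")
  if (abs(sum(mix) - 1) > 1e-8) stop("mix proportions must sum to 1")
  if (!all(names(mix) %in% names(profiles))) {
    stop("mix names must match profile names")
  }
  recs <- vector("list", n_dogs)
  tru <- vector("list", n_dogs)
  std_keys <- character(n_dogs)
  for (i in seq_len(n_dogs)) {
    ## assignment and trajectory use separate per-dog substreams
    set.seed(substream_seed(seed, 2L * i))
    profile_i <- sample(names(mix), 1, prob = mix)
    std_keys[i] <- sample(names(standards), 1)
    sim <- simulate_trajectory(
      standards[[std_keys[i]]], profiles[[profile_i]],
      dog_id = sprintf("dog%05d", i),
      seed = substream_seed(seed, 2L * i + 1L))
    recs[[i]] <- sim$records
    tru[[i]] <- cbind(sim$truth[, "dog_id"],
                      sex = standards[[std_keys[i]]]$sex,
                      size_class = standards[[std_keys[i]]]$size_class,
                      sim$truth[, c("profile", "start_z",
                                    "terminal_drift_z")])
  }
  list(records = dplyr::bind_rows(recs),
       truth = tibble::as_tibble(dplyr::bind_rows(tru)))
}

#' Inject measurement outliers into a cohort
#'
#' Perturbs a random subset of records with the error kinds real
#' weight data exhibit: doubling, halving, pounds recorded as
#' kilograms (x 0.45359237), and decimal shifts (x 10 or x 0.1).
#' Returns the contaminated records plus a truth table naming every
#' perturbed record, so cleaning sensitivity and false-positive rate
#' are self-scoring.
#'
#' @param records Record tibble (rows are records).
#' @param rate Perturbation probability per record, in [0, 0.2].
#' @param kinds Subset of `c("double", "half", "lb_as_kg",
#'   "decimal_shift")`.
#' @param seed Integer seed.
#' @return List with `records` (perturbed copy) and `truth` (tibble:
#'   `row`, `dog_id`, `kind`, `original_weight`).
#' @export
inject_outliers <- function(records, rate, kinds = c("double", "half",
                                                     "decimal_shift"),
                            seed = 1) {
  stopifnot(rate >= 0, rate <= 0.2)
  kinds <- match.arg(kinds, c("double", "half", "lb_as_kg",
                              "decimal_shift"), several.ok = TRUE)
  set.seed(seed)
  hit <- which(rbinom(nrow(records), 1, rate) == 1)
  truth <- tibble::tibble(row = integer(0), dog_id = character(0),
                          kind = character(0),
                          original_weight = numeric(0))
  if (length(hit) > 0) {
    kind <- sample(kinds, length(hit), replace = TRUE)
    factor <- vapply(kind, function(k) switch(
      k, double = 2, half = 0.5, lb_as_kg = 0.45359237,
      decimal_shift = sample(c(10, 0.1), 1)), numeric(1))
    truth <- tibble::tibble(row = hit, dog_id = records$dog_id[hit],
                            kind = kind,
                            original_weight = records$weight_kg[hit])
    records$weight_kg[hit] <- records$weight_kg[hit] * factor
  }
  list(records = records, truth = truth)
}
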