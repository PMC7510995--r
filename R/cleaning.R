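#' Eligibility filter for longitudinal weight records
#'
#' Applies the study-entry rules. Colony mode keeps dogs with at least
#' one bodyweight recorded between 0.20 and 2.25 years. Clinic mode
#' keeps dogs weighed at least 4 times, over a period of at least 3
#' months (0.25 y), between 12 weeks and 2 years of age; only records
#' inside that window count towards the visit and span requirements.
#'
#' @param records Data frame of weight records with at least `dog_id`,
#'   `age_years`, `weight_kg`.
#' @param mode `"clinic"` or `"colony"`.
#' @return List with `eligible` (records of eligible dogs) and
#'   `exclusions` (tibble `dog_id`, `reason`).
#' @export
eligibility_filter <- function(records, mode = c("clinic", "colony")) {
  mode <- match.arg(mode)
  if (nrow(records) == 0) {
    return(list(eligible = records,
                exclusions = tibble::tibble(dog_id = character(0),
                                            reason = character(0))))
  }
  if (mode == "colony") {
    window <- c(0.20, 2.25)
    min_visits <- 1L
    min_span <- 0
  } else {
    window <- c(weeks_to_years(12), 2.0)
    min_visits <- 4L
    min_span <- 0.25
  }
  in_win <- records$age_years >= window[1] & records$age_years <= window[2]
  per_dog <- dplyr::summarise(
    dplyr::group_by(records[in_win, , drop = FALSE], .data$dog_id),
    n_visits = dplyr::n(),
    span = max(.data$age_years) - min(.data$age_years),
    .groups = "drop")
  all_dogs <- unique(records$dog_id)
  per_dog <- merge(data.frame(dog_id = all_dogs), per_dog,
                   by = "dog_id", all.x = TRUE)
  per_dog$n_visits[is.na(per_dog$n_visits)] <- 0L
  per_dog$span[is.na(per_dog$span)] <- 0
  reason <- ifelse(per_dog$n_visits < min_visits, "too_few_visits",
                   ifelse(per_dog$span < min_span, "span_too_short", NA))
  excl <- tibble::tibble(dog_id = per_dog$dog_id[!is.na(reason)],
                         reason = reason[!is.na(reason)])
  list(eligible = records[!(records$dog_id %in% excl$dog_id), , drop = FALSE],
       exclusions = excl)
}

#' Binned box-and-whisker statistics of weight over age
#'
#' Divides the age range into `n_bins` equal-width categories and
#' computes, per bin, the median, type-7 quartiles, and Tukey whiskers
#' (the most extreme datum within 1.5 interquartile ranges of the
#' quartiles). Whisker lengths are measured from the median, so the
#' outlier bounds built on them can be asymmetric. Bins with fewer than
#' 5 records are flagged `low_support`.
#'
#' @param age,weight Record ages (years) and weights (kg).
#' @param n_bins Number of equal-width age categories.
#' @param age_range Length-2 age range to bin over; defaults to
#'   `c(0.20, 2.25)` years.
#' @return Data frame with one row per bin: `bin_index`, `age_mid`,
#'   `n`, `median_w`, `q1`, `q3`, `lower_whisker_len`,
#'   `upper_whisker_len`, `low_support`. Empty bins carry `NA`
#'   statistics.
#' @export
binned_boxwhisker <- function(age, weight, n_bins = 40,
                              age_range = c(0.20, 2.25)) {
  if (diff(age_range) <= 0) stop("empty age range")
  edges <- seq(age_range[1], age_range[2], length.out = n_bins + 1)
  mids <- (edges[-1] + edges[-(n_bins + 1)]) / 2
  idx <- findInterval(age, edges, rightmost.closed = TRUE)
  idx[idx < 1 | idx > n_bins] <- NA
  out <- data.frame(bin_index = seq_len(n_bins), age_mid = mids,
                    n = 0L, median_w = NA_real_, q1 = NA_real_,
                    q3 = NA_real_, lower_whisker_len = NA_real_,
                    upper_whisker_len = NA_real_, low_support = TRUE)
  for (b in seq_len(n_bins)) {
    w <- weight[!is.na(idx) & idx == b]
    if (length(w) == 0) next
    q <- stats::quantile(w, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    iqr <- q[3] - q[1]
    lo_fence <- q[1] - 1.5 * iqr
    hi_fence <- q[3] + 1.5 * iqr
    whisk_lo <- min(w[w >= lo_fence])
    whisk_hi <- max(w[w <= hi_fence])
    out$n[b] <- length(w)
    out$median_w[b] <- q[2]
    out$q1[b] <- q[1]
    out$q3[b] <- q[3]
    out$lower_whisker_len[b] <- q[2] - whisk_lo
    out$upper_whisker_len[b] <- whisk_hi - q[2]
    out$low_support[b] <- length(w) < 5
  }
  out
}

#' Smooth outlier bounds across age bins
#'
#' Fits three locally-weighted linear (loess, tricube) curves over the
#' bin mid-ages: one through the bin medians and one through each of
#' median plus/minus 150 percent of the respective whisker length.
#' Sparse bins are down-weighted in proportion to the square root of
#' their record count. The smoothed upper and lower curves are the
#' population outlier bounds; the lower bound is floored at a small
#' positive weight.
#'
#' @param bins Output of [binned_boxwhisker()].
#' @param span Loess span over the bin mid-ages (default 0.5).
#' @param whisker_factor Multiplier on the whisker lengths (default 1.5,
#'   i.e. 150 percent).
#' @param floor_kg Minimum allowed lower bound (default 0.05 kg).
#' @return `bins` with added columns `smoothed_median`,
#'   `smoothed_lower_bound`, `smoothed_upper_bound` (NA for bins whose
#'   mid-age the fit does not cover).
#' @export
smooth_outlier_bounds <- function(bins, span = 0.5, whisker_factor = 1.5,
                                  floor_kg = 0.05) {
  use <- !is.na(bins$median_w)
  n_use <- sum(use)
  if (n_use < 4) {
    stop("fewer than 4 usable age bins; supply more data or fewer bins")
  }
  x <- bins$age_mid[use]
  w <- sqrt(bins$n[use])
  span_eff <- min(1, max(span, 5 / n_use))
  fit_curve <- function(y) {
    fit <- stats::loess(y ~ x, weights = w, span = span_eff, degree = 1,
                        family = "gaussian",
                        control = stats::loess.control(surface = "direct"))
    stats::predict(fit, newdata = data.frame(x = bins$age_mid))
  }
  med <- bins$median_w[use]
  up_raw <- med + whisker_factor * bins$upper_whisker_len[use]
  lo_raw <- med - whisker_factor * bins$lower_whisker_len[use]
  bins$smoothed_median <- fit_curve(med)
  bins$smoothed_upper_bound <- fit_curve(up_raw)
  bins$smoothed_lower_bound <- pmax(fit_curve(lo_raw), floor_kg)
  bad <- !is.na(bins$smoothed_lower_bound) &
    !is.na(bins$smoothed_upper_bound) &
    bins$smoothed_lower_bound >= bins$smoothed_upper_bound
  if (any(bad)) {
    mid <- (bins$smoothed_lower_bound[bad] + bins$smoothed_upper_bound[bad]) / 2
    eps <- 1e-6
    bins$smoothed_lower_bound[bad] <- mid - eps
    bins$smoothed_upper_bound[bad] <- mid + eps
  }
  bins
}

#' Flag population-level weight outliers
#'
#' A record is an outlier when its weight lies strictly above the
#' smoothed upper bound or strictly below the smoothed lower bound at
#' its age (bounds linearly interpolated between bin mid-ages, held
#' flat beyond the outermost mids). A weight exactly on a bound is
#' kept.
#'
#' @param records Data frame with `age_years`, `weight_kg`.
#' @param bins Output of [smooth_outlier_bounds()].
#' @return Tibble with `outlier` (logical), `lower_bound`,
#'   `upper_bound`, one row per record.
#' @export
flag_population_outliers <- function(records, bins) {
  if (nrow(records) == 0) {
    return(tibble::tibble(outlier = logical(0), lower_bound = numeric(0),
                          upper_bound = numeric(0)))
  }
  use <- !is.na(bins$smoothed_upper_bound)
  lo <- stats::approx(bins$age_mid[use], bins$smoothed_lower_bound[use],
                      xout = records$age_years, rule = 2)$y
  hi <- stats::approx(bins$age_mid[use], bins$smoothed_upper_bound[use],
                      xout = records$age_years, rule = 2)$y
  tibble::tibble(outlier = records$weight_kg > hi | records$weight_kg < lo,
                 lower_bound = lo, upper_bound = hi)
}

#' Flag gross outliers within an individual growth curve
#'
#' A visit is flagged when its z-score deviates from the median z of
#' its nearest neighbours (a window of up to 2 visits on each side,
#' clipped at the trajectory ends, the visit itself excluded) by more
#' than `tau`. Trajectories with fewer than 3 visits provide no
#' context and are never flagged.
#'
#' @param z z-scores of one dog's visits, in age order.
#' @param tau Deviation threshold in z units (default 1.5).
#' @param window Neighbours considered on each side (default 2).
#' @return Tibble with `outlier` (logical) and `deviation` (z units).
#' @export
flag_individual_gross_outliers <- function(z, tau = 1.5, window = 2) {
  n <- length(z)
  if (n < 3) {
    return(tibble::tibble(outlier = rep(FALSE, n),
                          deviation = rep(NA_real_, n)))
  }
  dev <- vapply(seq_len(n), function(i) {
    nb <- setdiff(max(1, i - window):min(n, i + window), i)
    z[i] - stats::median(z[nb])
  }, numeric(1))
  tibble::tibble(outlier = abs(dev) > tau, deviation = dev)
}

#' Exclude trajectories lying entirely beyond the outermost centiles
#'
#' A dog whose kept visits are all strictly above the 99.6 percent
#' centile line, or all strictly below the 0.4 percent line, is
#' excluded: such a trajectory most plausibly reflects a misidentified
#' breed (the wrong standard), not extreme growth.
#'
#' @param z Kept z-scores of one dog.
#' @param chart A [centile_chart()]; its outermost lines define the rule.
#' @return `"eligible"`, `"trajectory_above_99.6"` or
#'   `"trajectory_below_0.4"`.
#' @export
exclude_extreme_trajectories <- function(z, chart = centile_chart()) {
  z <- z[!is.na(z)]
  if (length(z) == 0) return("eligible")
  hi <- max(chart$z_lines)
  lo <- min(chart$z_lines)
  if (all(z > hi)) return("trajectory_above_99.6")
  if (all(z < lo)) return("trajectory_below_0.4")
  "eligible"
}

#' Clean a longitudinal weight cohort
#'
#' Runs the full cleaning cascade: size-class assignment, eligibility
#' filtering, per-stratum (sex by size class) binned box-whisker
#' population outlier removal with loess-smoothed bounds, per-dog
#' gross-outlier removal on the z-score scale, and exclusion of
#' trajectories lying entirely beyond the outermost centile lines.
#' Every input record is accounted for exactly once in the report.
#'
#' Strata with too few usable age bins to estimate population bounds
#' (fewer than 4) skip the population-outlier stage with a warning;
#' the individual-level rules still apply there.
#'
#' @param records Record data frame with columns `dog_id`, `sex`,
#'   `age_years`, `weight_kg` and optionally `breed`, `mixed_breed`,
#'   `size_class`, `adult_weight_kg`.
#' @param standards Named list of `growth_standard` objects keyed
#'   `"<sex>.<size_class>"` (as from [load_standards()]).
#' @param breed_map Optional breed-to-class table (columns `breed`,
#'   `size_class`); needed only when `size_class` is missing from the
#'   records.
#' @param mode Eligibility mode, `"clinic"` or `"colony"`.
#' @param n_bins,span Binning and smoothing controls, see
#'   [binned_boxwhisker()] and [smooth_outlier_bounds()].
#' @param tau_ind Individual gross-outlier threshold in z units.
#' @param chart Centile chart for the extreme-trajectory rule.
#' @param age_range Age range for binning.
#' @param min_stratum_records Minimum records a stratum needs before
#'   population bounds are estimated for it (default 50): box-whisker
#'   bounds from a handful of records would be dominated by sampling
#'   noise, so thin strata skip that stage (with a warning) and rely
#'   on the individual-level rules.
#' @return List with `clean` (kept records, with a `z` column) and
#'   `report` (list: `record_flags`, `dog_exclusions`, `counts`).
#' @export
clean_dataset <- function(records, standards, breed_map = NULL,
                          mode = c("clinic", "colony"), n_bins = 40,
                          span = 0.5, tau_ind = 1.5,
                          chart = centile_chart(),
                          age_range = c(0.20, 2.25),
                          min_stratum_records = 50) {
  mode <- match.arg(mode)
  empty_report <- list(
    record_flags = tibble::tibble(record_id = integer(0),
                                  dog_id = character(0),
                                  status = character(0),
                                  lower_bound = numeric(0),
                                  upper_bound = numeric(0),
                                  deviation = numeric(0)),
    dog_exclusions = tibble::tibble(dog_id = character(0),
                                    reason = character(0)),
    counts = list(n_records_in = 0L, n_dogs_in = 0L,
                  n_records_kept = 0L, n_dogs_kept = 0L))
  if (nrow(records) == 0) {
    return(list(clean = records, report = empty_report))
  }

  records$record_id <- seq_len(nrow(records))
  status <- rep("kept", nrow(records))
  lower_bound <- rep(NA_real_, nrow(records))
  upper_bound <- rep(NA_real_, nrow(records))
  deviation <- rep(NA_real_, nrow(records))
  dog_excl <- tibble::tibble(dog_id = character(0), reason = character(0))

  mark_dog_excluded <- function(ids, reason) {
    new <- setdiff(ids, dog_excl$dog_id)
    if (length(new) > 0) {
      dog_excl <<- rbind(dog_excl,
                         tibble::tibble(dog_id = new, reason = reason))
      status[records$dog_id %in% new & status == "kept"] <<- "dog_excluded"
    }
  }

  ## --- size-class assignment (dog level) ---
  if (is.null(records$size_class)) records$size_class <- NA_character_
  need <- is.na(records$size_class) | records$size_class == ""
  if (any(need)) {
    dogs <- unique(records$dog_id[need])
    first <- records[match(dogs, records$dog_id), , drop = FALSE]
    asg <- assign_size_class(
      breed = if (is.null(first$breed)) NA else first$breed,
      mixed_breed = if (is.null(first$mixed_breed)) TRUE else first$mixed_breed,
      adult_weight = if (is.null(first$adult_weight_kg)) NA else
        first$adult_weight_kg,
      breed_map = if (is.null(breed_map))
        data.frame(breed = character(0), size_class = character(0)) else
          breed_map)
    records$size_class[need] <-
      asg$size_class[match(records$dog_id[need], dogs)]
    mark_dog_excluded(dogs[is.na(asg$size_class)], "unmapped_class")
  }

  ## --- eligibility (dog level) ---
  active <- records[status == "kept", , drop = FALSE]
  elig <- eligibility_filter(active, mode)
  if (nrow(elig$exclusions) > 0) {
    for (r in unique(elig$exclusions$reason)) {
      mark_dog_excluded(elig$exclusions$dog_id[elig$exclusions$reason == r], r)
    }
  }

  ## --- population outliers, per sex x size-class stratum ---
  active_idx <- which(status == "kept")
  strata <- unique(records[active_idx, c("sex", "size_class")])
  for (k in seq_len(nrow(strata))) {
    sel <- active_idx[records$sex[active_idx] == strata$sex[k] &
                        records$size_class[active_idx] == strata$size_class[k]]
    if (length(sel) == 0) next
    if (length(sel) < min_stratum_records) {
      warning(sprintf(
        "stratum %s/%s has %d records (< %d); population-outlier stage skipped",
        strata$sex[k], strata$size_class[k], length(sel),
        min_stratum_records))
      next
    }
    bb <- binned_boxwhisker(records$age_years[sel], records$weight_kg[sel],
                            n_bins = n_bins, age_range = age_range)
    sb <- tryCatch(smooth_outlier_bounds(bb, span = span),
                   error = function(e) NULL)
    if (is.null(sb)) {
      warning(sprintf(
        "stratum %s/%s: too few bins for population bounds; stage skipped",
        strata$sex[k], strata$size_class[k]))
      next
    }
    fl <- flag_population_outliers(records[sel, , drop = FALSE], sb)
    status[sel][fl$outlier] <- "population_outlier"
    lower_bound[sel] <- fl$lower_bound
    upper_bound[sel] <- fl$upper_bound
  }

  ## --- z-scores for surviving records ---
  z <- rep(NA_real_, nrow(records))
  for (key in unique(std_key(records$sex, records$size_class))) {
    std <- standards[[key]]
    sel <- which(std_key(records$sex, records$size_class) == key &
                   status %in% c("kept", "population_outlier"))
    if (is.null(std) || length(sel) == 0) next
    rng <- range(std$age_grid)
    ok <- sel[records$age_years[sel] >= rng[1] &
                records$age_years[sel] <= rng[2]]
    if (length(ok) > 0) {
      z[ok] <- weight_to_z(std, records$age_years[ok], records$weight_kg[ok])
    }
  }

  ## --- individual gross outliers (on kept visits, in age order) ---
  kept_idx <- which(status == "kept")
  for (d in unique(records$dog_id[kept_idx])) {
    sel <- kept_idx[records$dog_id[kept_idx] == d]
    sel <- sel[order(records$age_years[sel])]
    zi <- z[sel]
    if (any(is.na(zi))) next
    fl <- flag_individual_gross_outliers(zi, tau = tau_ind)
    status[sel][fl$outlier] <- "individual_gross_outlier"
    deviation[sel] <- fl$deviation
  }

  ## --- extreme trajectories (dog level, kept z only) ---
  kept_idx <- which(status == "kept")
  for (d in unique(records$dog_id[kept_idx])) {
    sel <- kept_idx[records$dog_id[kept_idx] == d]
    verdict <- exclude_extreme_trajectories(z[sel], chart)
    if (verdict != "eligible") mark_dog_excluded(d, verdict)
  }
  ## dogs whose every record was flagged at record level
  flagged_only <- setdiff(unique(records$dog_id),
                          c(unique(records$dog_id[status == "kept"]),
                            dog_excl$dog_id))
  if (length(flagged_only) > 0) {
    dog_excl <- rbind(dog_excl, tibble::tibble(dog_id = flagged_only,
                                               reason = "no_kept_records"))
  }

  records$z <- z
  keep <- status == "kept"
  report <- list(
    record_flags = tibble::tibble(
      record_id = records$record_id, dog_id = records$dog_id,
      status = status, lower_bound = lower_bound,
      upper_bound = upper_bound, deviation = deviation),
    dog_exclusions = dog_excl,
    counts = list(
      n_records_in = nrow(records),
      n_dogs_in = length(unique(records$dog_id)),
      n_records_kept = sum(keep),
      n_dogs_kept = length(unique(records$dog_id[keep])),
      n_population_outliers = sum(status == "population_outlier"),
      n_individual_outliers = sum(status == "individual_gross_outlier"),
      n_records_of_excluded_dogs = sum(status == "dog_excluded")))
  list(clean = records[keep, , drop = FALSE], report = report)
}
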