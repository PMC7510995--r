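#' Construct a growth standard
#'
#' A growth standard is an age-gridded LMS (Box-Cox power `L`, median `M`,
#' coefficient of variation `S`) representation of the weight-for-age
#' reference distribution for one sex and one adult size class. `L`
#' controls skewness, `M` is the median weight in kg and `S` the
#' coefficient of variation, each tabulated on a strictly increasing age
#' grid in decimal years.
#'
#' @param sex `"male"` or `"female"`.
#' @param size_class One of `"I"`..`"V"` (adult-bodyweight categories
#'   from under 6.5 kg up to under 40 kg).
#' @param age_grid Strictly increasing ages in years.
#' @param L,M,S Numeric vectors, one value per grid age; `M > 0`, `S > 0`.
#' @param check_monotone_M Assert that `M` is non-decreasing (weights
#'   grow); enabled for synthetic standards.
#' @return An object of class `growth_standard`.
#' @export
growth_standard <- function(sex, size_class, age_grid, L, M, S,
                            check_monotone_M = TRUE) {
  sex <- match.arg(sex, c("male", "female"))
  size_class <- match.arg(size_class, c("I", "II", "III", "IV", "V"))
  n <- length(age_grid)
  stopifnot(length(L) == n, length(M) == n, length(S) == n, n >= 2)
  if (any(diff(age_grid) <= 0)) {
    stop("age_grid must be strictly increasing")
  }
  if (any(M <= 0)) stop("all M (median weight) must be positive")
  if (any(S <= 0)) stop("all S (coefficient of variation) must be positive")
  if (check_monotone_M && any(diff(M) < -1e-9)) {
    stop("M must be non-decreasing over the growth grid")
  }
  structure(
    list(sex = sex, size_class = size_class,
         age_grid = as.numeric(age_grid),
         L = as.numeric(L), M = as.numeric(M), S = as.numeric(S)),
    class = "growth_standard"
  )
}

#' @export
print.growth_standard <- function(x, ...) {
  cat(sprintf(
    "<growth_standard> sex=%s size_class=%s ages [%.2f, %.2f] y (%d grid points)\n",
    x$sex, x$size_class, min(x$age_grid), max(x$age_grid),
    length(x$age_grid)))
  invisible(x)
}

std_key <- function(sex, size_class) paste(sex, size_class, sep = ".")

#' Load a collection of growth standards from CSV
#'
#' Reads a standards table with header
#' `sex,size_class,age_years,L,M,S` (one row per grid age) and returns a
#' named list of [growth_standard()] objects, one per (sex, size class)
#' present, keyed `"<sex>.<size_class>"`.
#'
#' @param path Path to the standards CSV file.
#' @return Named list of `growth_standard` objects.
#' @export
load_standards <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("sex", "size_class", "age_years", "L", "M", "S")
  missing <- setdiff(required, names(tab))
  if (length(missing) > 0) {
    stop("standards file is missing column(s): ",
         paste(missing, collapse = ", "))
  }
  out <- list()
  for (sx in unique(tab$sex)) {
    for (cl in unique(tab$size_class[tab$sex == sx])) {
      sub <- tab[tab$sex == sx & tab$size_class == cl, , drop = FALSE]
      sub <- sub[order(sub$age_years), , drop = FALSE]
      dup <- which(diff(sub$age_years) == 0)
      if (length(dup) > 0) {
        stop(sprintf("duplicated age %g for sex=%s size_class=%s",
                     sub$age_years[dup[1]], sx, cl))
      }
      bad <- which(sub$M <= 0 | sub$S <= 0)
      if (length(bad) > 0) {
        stop(sprintf(
          "non-positive M or S at age %g for sex=%s size_class=%s",
          sub$age_years[bad[1]], sx, cl))
      }
      out[[std_key(sx, cl)]] <- growth_standard(
        sx, cl, sub$age_years, sub$L, sub$M, sub$S,
        check_monotone_M = FALSE)
    }
  }
  out
}

#' Write a collection of growth standards to CSV
#'
#' @param standards Named list of `growth_standard` objects.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_standards <- function(standards, path) {
  rows <- lapply(standards, function(s) {
    data.frame(sex = s$sex, size_class = s$size_class,
               age_years = s$age_grid, L = s$L, M = s$M, S = s$S)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Evaluate LMS parameters at arbitrary ages
#'
#' Interpolates the standard's (L, M, S) at continuous ages: the median
#' `M` with a monotone piecewise-cubic (Fritsch-Carlson) interpolant so
#' median growth stays monotone without overshoot, `L` and `S`
#' linearly. Exact at grid points. Ages outside the grid are an error:
#' the standard is defined only for the growth phase, so there is no
#' extrapolation.
#'
#' @param std A `growth_standard`.
#' @param age Ages in years (vectorized).
#' @return A list with numeric vectors `L`, `M`, `S`.
#' @export
interpolate_lms <- function(std, age) {
  rng <- range(std$age_grid)
  if (any(age < rng[1] - 1e-12 | age > rng[2] + 1e-12)) {
    stop(sprintf(
      "age outside the standard's grid [%.3f, %.3f]; no extrapolation",
      rng[1], rng[2]))
  }
  age <- pmin(pmax(age, rng[1]), rng[2])
  mfun <- stats::splinefun(std$age_grid, std$M, method = "monoH.FC")
  list(
    L = stats::approx(std$age_grid, std$L, xout = age)$y,
    M = mfun(age),
    S = stats::approx(std$age_grid, std$S, xout = age)$y
  )
}

lms_z <- function(weight, L, M, S) {
  n <- max(length(weight), length(L))
  weight <- rep_len(weight, n)
  L <- rep_len(L, n)
  M <- rep_len(M, n)
  S <- rep_len(S, n)
  out <- numeric(n)
  zero <- abs(L) < 1e-12
  out[zero] <- log(weight[zero] / M[zero]) / S[zero]
  out[!zero] <- ((weight[!zero] / M[!zero])^L[!zero] - 1) /
    (L[!zero] * S[!zero])
  out
}

lms_weight <- function(z, L, M, S) {
  n <- max(length(z), length(L))
  z <- rep_len(z, n)
  L <- rep_len(L, n)
  M <- rep_len(M, n)
  S <- rep_len(S, n)
  bad <- abs(L) >= 1e-12 & (1 + L * S * z) <= 0
  if (any(bad)) {
    stop("z outside the invertible LMS domain (1 + L*S*z must be positive)")
  }
  out <- numeric(n)
  zero <- abs(L) < 1e-12
  out[zero] <- M[zero] * exp(S[zero] * z[zero])
  out[!zero] <- M[!zero] *
    (1 + L[!zero] * S[!zero] * z[!zero])^(1 / L[!zero])
  out
}

#' Convert a weight to a weight-for-age z-score
#'
#' Applies the LMS transform at the record's age:
#' `z = ((w/M)^L - 1) / (L*S)` for `L != 0` and `z = log(w/M)/S` for
#' `L = 0`. Strictly increasing in weight at fixed age.
#'
#' @param std A `growth_standard`.
#' @param age Ages in years (vectorized with `weight`).
#' @param weight Weights in kg, positive.
#' @return z-scores.
#' @export
weight_to_z <- function(std, age, weight) {
  if (any(weight <= 0)) stop("weight must be positive")
  p <- interpolate_lms(std, age)
  lms_z(weight, p$L, p$M, p$S)
}

#' Convert a z-score back to a weight
#'
#' Exact inverse of [weight_to_z()]: `w = M * (1 + L*S*z)^(1/L)` for
#' `L != 0`, `w = M * exp(S*z)` for `L = 0`. Used to draw centile
#' curves on the weight scale and to synthesize weights from latent
#' z trajectories.
#'
#' @param std A `growth_standard`.
#' @param age Ages in years.
#' @param z z-scores; must satisfy `1 + L*S*z > 0` when `L != 0`.
#' @return Weights in kg.
#' @export
z_to_weight <- function(std, age, z) {
  p <- interpolate_lms(std, age)
  lms_weight(z, p$L, p$M, p$S)
}

#' The centile chart's line geometry
#'
#' Builds the set of centile lines a growth chart draws, as standard
#' normal quantiles of the centile levels. The default is the
#' nine-centile chart at 0.4, 2, 9, 25, 50, 75, 91, 98 and 99.6
#' percent, whose inner lines are two-thirds of a z-score apart
#' (the "channel" width).
#'
#' @param levels Centile levels as probabilities in (0, 1), strictly
#'   increasing.
#' @return An object of class `centile_chart` with fields
#'   `centile_levels` and `z_lines`.
#' @export
centile_chart <- function(levels = c(0.004, 0.02, 0.09, 0.25, 0.50,
                                     0.75, 0.91, 0.98, 0.996)) {
  levels <- as.numeric(levels)
  if (any(levels <= 0 | levels >= 1)) {
    stop("centile levels must lie strictly inside (0, 1)")
  }
  if (any(diff(levels) <= 0)) {
    stop("centile levels must be strictly increasing")
  }
  structure(
    list(centile_levels = levels, z_lines = stats::qnorm(levels)),
    class = "centile_chart"
  )
}

#' @export
print.centile_chart <- function(x, ...) {
  cat("<centile_chart>", length(x$z_lines), "lines at",
      paste0(format(100 * x$centile_levels, trim = TRUE), "%",
             collapse = ", "), "\n")
  invisible(x)
}

#' Size-class boundaries by adult weight
#'
#' Assigns the adult-bodyweight category: I (<6.5 kg), II (6.5 to
#' <9 kg), III (9 to <15 kg), IV (15 to <30 kg), V (30 to <40 kg).
#' Intervals are closed on the left and open on the right. Weights of
#' 40 kg and above fall outside the charted range and return `NA`.
#'
#' @param adult_weight Adult weight in kg.
#' @return Character vector of classes, `NA` where out of range.
#' @export
size_class_from_weight <- function(adult_weight) {
  breaks <- c(-Inf, 6.5, 9, 15, 30, 40)
  cls <- c("I", "II", "III", "IV", "V")
  idx <- findInterval(adult_weight, breaks, left.open = FALSE)
  out <- ifelse(idx >= 1 & idx <= 5, cls[pmin(idx, 5L)], NA_character_)
  out[adult_weight >= 40] <- NA_character_
  out[adult_weight <= 0] <- NA_character_
  out
}

#' Assign dogs to size classes
#'
#' Pedigree dogs are mapped through a user-supplied breed-to-class
#' table; mixed-breed dogs are categorised by final adult weight when
#' available and otherwise excluded. Mixed-breed adult weights of 40 kg
#' or more fall above the class V ceiling and are excluded too.
#'
#' @param breed Breed name, or `NA`.
#' @param mixed_breed Logical: is the dog mixed breed?
#' @param adult_weight Final adult weight in kg, or `NA`.
#' @param breed_map Data frame with columns `breed`, `size_class`.
#' @return A list with `size_class` (character, `NA` if excluded) and
#'   `reason` (`NA` if assigned; otherwise one of `"unmapped breed"`,
#'   `"no adult weight"`, `"adult weight out of range"`).
#' @export
assign_size_class <- function(breed, mixed_breed, adult_weight, breed_map) {
  n <- max(length(breed), length(mixed_breed), length(adult_weight))
  breed <- rep_len(breed, n)
  mixed_breed <- rep_len(as.logical(mixed_breed), n)
  adult_weight <- rep_len(adult_weight, n)
  cls <- rep(NA_character_, n)
  reason <- rep(NA_character_, n)

  ped <- !mixed_breed & !is.na(breed) & breed != ""
  if (any(ped)) {
    m <- match(breed[ped], breed_map$breed)
    cls[ped] <- breed_map$size_class[m]
    reason[ped][is.na(m)] <- "unmapped breed"
  }
  mix <- !ped
  has_w <- mix & !is.na(adult_weight)
  cls[has_w] <- size_class_from_weight(adult_weight[has_w])
  reason[has_w & is.na(cls)] <- "adult weight out of range"
  reason[mix & is.na(adult_weight)] <- "no adult weight"
  list(size_class = cls, reason = reason)
}

#' Conversion between weeks and decimal years
#'
#' The analyses use decimal years throughout; week-denominated inputs
#' (visit schedules, eligibility windows) are converted at I/O with
#' 1 year = 52.1775 weeks.
#'
#' @param weeks Ages in weeks.
#' @return Ages in years.
#' @export
weeks_to_years <- function(weeks) weeks / 52.1775
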