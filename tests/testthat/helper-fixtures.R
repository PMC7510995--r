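# shared fixtures and independent oracles, built in code at test time

test_standard <- function(L = -0.2) {
  make_reference_standard("III", "male", L = L)
}

# flat standard with constant LMS, handy for hand-computable z values
const_standard <- function(L, M, S) {
  growth_standard("male", "III", age_grid = c(0, 3),
                  L = rep(L, 2), M = rep(M, 2), S = rep(S, 2),
                  check_monotone_M = FALSE)
}

# independent crossing oracle: enumerate every (visit, line) pair
brute_force_crossings <- function(z, lines) {
  z1 <- z[1]
  up <- 0L
  down <- 0L
  for (j in seq_along(z)[-1]) {
    u <- 0L
    d <- 0L
    for (l in lines) {
      if (l > z1 && l < z[j]) u <- u + 1L
      if (l < z1 && l > z[j]) d <- d + 1L
    }
    up <- max(up, u)
    down <- max(down, d)
  }
  list(up = up, down = down, total = max(up, down))
}

# high-precision quadrature oracle for the inverse normal CDF
qnorm_quadrature <- function(p) {
  vapply(p, function(pp) {
    stats::uniroot(function(q) {
      stats::integrate(stats::dnorm, -Inf, q,
                       rel.tol = 1e-13)$value - pp
    }, c(-10, 10), tol = 1e-13)$root
  }, numeric(1))
}

# small record tibble for one dog
dog_records <- function(dog_id, ages, weights, sex = "male",
                        size_class = "III", group = "g") {
  tibble::tibble(dog_id = dog_id, sex = sex, breed = "synthetic",
                 mixed_breed = FALSE, size_class = size_class,
                 adult_weight_kg = NA_real_, age_years = ages,
                 weight_kg = weights, visit_type = NA_character_,
                 bcs_label = NA_character_, diagnosis = NA_character_,
                 group = group)
}
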