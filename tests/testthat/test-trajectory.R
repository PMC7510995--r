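test_that("penalized-t fit recovers flat and sinusoidal median curves", {
  set.seed(2)
  age <- runif(2000, 0.25, 2)
  flat <- fit_z_curve(data.frame(age_years = age, z = rt(2000, 5)))
  mu <- predict_median(flat, seq(0.3, 1.95, length.out = 60))$z_median
  expect_lt(max(abs(mu)), 0.1)
  expect_gt(flat$sigma, 0)
  expect_gte(flat$edf, 2)

  set.seed(3)
  age2 <- runif(5000, 0.2, 2.2)
  true_mu <- function(a) 0.5 * sin(2 * pi * a / 2)
  z2 <- true_mu(age2) + rnorm(5000, 0, 0.3)
  f2 <- fit_z_curve(data.frame(age_years = age2, z = z2))
  ag <- seq(0.25, 2.15, length.out = 100)
  rmse <- sqrt(mean((predict_median(f2, ag)$z_median - true_mu(ag))^2))
  expect_lte(rmse, 0.08)
})

test_that("the infinite-penalty limit is a straight line and SBC picks the grid minimum", {
  set.seed(4)
  age <- runif(1500, 0.2, 2.2)
  z <- 0.5 * sin(2 * pi * age / 2) + rnorm(1500, 0, 0.3)
  f <- fit_z_curve(data.frame(age_years = age, z = z),
                   lambda_grid = 1e12, nu_grid = Inf)
  ag <- seq(0.25, 2.15, length.out = 80)
  pr <- predict_median(f, ag)$z_median
  expect_lt(max(abs(resid(lm(pr ~ ag)))), 1e-5)
  expect_equal(f$edf, 2, tolerance = 1e-3)

  # edf decreases along an increasing lambda path
  edfs <- vapply(c(0.1, 10, 1000, 1e5), function(l) {
    fit_z_curve(data.frame(age_years = age, z = z), lambda_grid = l,
                nu_grid = Inf)$edf
  }, numeric(1))
  expect_true(all(diff(edfs) < 0))

  # the selected lambda minimises SBC over its grid
  grid <- 10^seq(-1, 5, length.out = 15)
  fsel <- fit_z_curve(data.frame(age_years = age, z = z),
                      lambda_grid = grid, nu_grid = Inf)
  sbcs <- vapply(grid, function(l) {
    fit_z_curve(data.frame(age_years = age, z = z), lambda_grid = l,
                nu_grid = Inf)$sbc
  }, numeric(1))
  expect_equal(fsel$sbc, min(sbcs), tolerance = 1e-6)
})

test_that("large t degrees of freedom recover the Gaussian fit", {
  set.seed(5)
  age <- runif(1200, 0.2, 2.2)
  z <- 0.3 * age + rnorm(1200, 0, 0.4)
  ag <- seq(0.25, 2.1, length.out = 50)
  fa <- fit_z_curve(data.frame(age_years = age, z = z), nu_grid = 1e6)
  fb <- fit_z_curve(data.frame(age_years = age, z = z), nu_grid = Inf)
  expect_lt(max(abs(predict_median(fa, ag)$z_median -
                      predict_median(fb, ag)$z_median)), 1e-4)
})

test_that("fitted median curves agree with an independent penalized scaled-t fit", {
  skip_if_not_installed("mgcv")
  set.seed(6)
  age <- runif(3000, 0.2, 2.2)
  z <- 0.5 * sin(2 * pi * age / 2) + 0.3 * rt(3000, 6)
  f <- fit_z_curve(data.frame(age_years = age, z = z))
  g <- mgcv::gam(z ~ s(age, bs = "ps", k = 20), family = mgcv::scat())
  ag <- seq(0.3, 2.1, length.out = 50)
  expect_lt(max(abs(predict_median(f, ag)$z_median -
                      as.numeric(predict(g, data.frame(age = ag))))),
            0.05)
})

test_that("predict_median maps z to centiles and respects the domain", {
  set.seed(7)
  age <- runif(600, 0.3, 2)
  f <- fit_z_curve(data.frame(age_years = age, z = rnorm(600, 0, 0.5)))
  p <- predict_median(f, c(0.5, 1.0))
  expect_equal(p$centile, 100 * pnorm(p$z_median))
  # evaluation converges at the domain edge
  edge <- f$age_domain[2]
  inner <- predict_median(f, edge - c(1e-3, 1e-5, 1e-7))$z_median
  at_edge <- predict_median(f, edge)$z_median
  expect_lt(abs(inner[3] - at_edge), 1e-3)
  expect_error(predict_median(f, 3), "domain")
  # mu = 0.674 sits near the 75th centile
  expect_equal(100 * pnorm(0.6744898), 75, tolerance = 0.01)
})

test_that("worm plots are calibrated under the truth and bend under misfit scale", {
  set.seed(8)
  r <- rnorm(10000)
  age <- runif(10000, 0.2, 2)
  w <- worm_plot_data(r, age, n_panels = 4)
  expect_gte(mean(abs(w$worm) <= w$envelope), 0.95)

  # variance inflated 1.5x: the worm rises on the right, falls on the left
  w2 <- worm_plot_data(1.5 * r, age, n_panels = 1)
  slope <- coef(lm(w2$worm ~ w2$x))[2]
  expect_gt(slope, 0.3)

  # one panel is a plain detrended QQ plot
  w1 <- worm_plot_data(r[1:100], age[1:100], n_panels = 1)
  expect_equal(unique(w1$panel), 1)
  expect_equal(w1$worm, sort(r[1:100]) - qnorm(stats::ppoints(100)),
               tolerance = 1e-9)
})

test_that("Q statistics are non-negative and reject gross location misfit", {
  set.seed(9)
  r <- rnorm(1000)
  age <- runif(1000, 0.2, 2)
  q <- q_statistics(r, age, n_bins = 4)
  expect_true(all(q$table$Q >= 0))
  expect_setequal(q$table$moment,
                  c("mean", "variance", "skewness", "kurtosis"))

  q_shift <- q_statistics(r + 1, age, n_bins = 4)
  expect_lt(q_shift$table$p[q_shift$table$moment == "mean"], 1e-6)

  w <- testthat::capture_warnings(
    q_statistics(rnorm(38), runif(38, 0, 2), n_bins = 4,
                 min_per_bin = 10))
  expect_true(any(grepl("dropped", w)))
})

test_that("mixed-model contrasts recover simulated differences and collapse correctly", {
  set.seed(10)
  mk <- function(g, mu, ndogs = 30, nvis = 10, su = 0.5, se = 0.3) {
    u <- rnorm(ndogs, 0, su)
    tibble::tibble(
      dog_id = rep(paste0(g, seq_len(ndogs)), each = nvis), group = g,
      z = mu + rep(u, each = nvis) + rnorm(ndogs * nvis, 0, se))
  }
  dat <- dplyr::bind_rows(mk("a", 0), mk("b", 1))
  mm <- mixed_model_compare(dat, "group")
  ct <- mm$contrasts
  expect_equal(abs(ct$estimate), 1, tolerance = 0.35)
  expect_true(ct$lower <= ct$estimate && ct$estimate <= ct$upper)
  expect_equal(mm$variance$sigma_u, 0.5, tolerance = 0.25)

  # identical groups: estimate ~ 0, adjusted p near 1
  dat0 <- dplyr::bind_rows(mk("a", 0.5), mk("b", 0.5))
  mm0 <- mixed_model_compare(dat0, "group")
  expect_lt(abs(mm0$contrasts$estimate), 0.4)
  expect_gt(mm0$contrasts$p_adj, 0.05)

  # one record per dog: estimates equal one-way ANOVA Tukey estimates
  set.seed(11)
  one <- tibble::tibble(
    dog_id = paste0("d", 1:90),
    group = rep(c("a", "b", "c"), each = 30),
    z = rep(c(0, 0.5, 1), each = 30) + rnorm(90, 0, 0.5))
  mm1 <- suppressWarnings(suppressMessages(
    mixed_model_compare(one, "group")))
  tk <- TukeyHSD(aov(z ~ group, data = one))$group
  got <- mm1$contrasts$estimate
  names(got) <- mm1$contrasts$contrast
  expect_equal(unname(abs(got[c("a - b", "a - c", "b - c")])),
               unname(abs(tk[c("b-a", "c-a", "c-b"), "diff"])),
               tolerance = 1e-6)
})
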