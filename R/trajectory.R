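#' @importFrom stats approx dnorm lm loess median pchisq pnorm pt qnorm
#'   quantile rbinom rnorm runif sd var
#' @importFrom dplyr .data
NULL

## equally spaced B-spline design over [a, b], knots extended beyond
## the boundary (Eilers-Marx construction) so the second-difference
## penalty's null space maps exactly onto straight lines
pspline_basis <- function(domain, n_knots = 20, degree = 3) {
  a <- domain[1]; b <- domain[2]
  h <- (b - a) / (n_knots + 1)
  knots <- seq(a - degree * h, by = h,
               length.out = n_knots + 2 * degree + 2)
  list(knots = knots, degree = degree, domain = domain,
       k = n_knots + degree + 1)
}

eval_basis <- function(basis, x) {
  if (any(x < basis$domain[1] - 1e-8 | x > basis$domain[2] + 1e-8)) {
    stop("age outside the fitted age domain")
  }
  ord <- basis$degree + 1
  nk <- length(basis$knots)
  ## clamp to the spline's exact support (guards fp drift at the edges)
  x <- pmin(pmax(x, basis$knots[ord]), basis$knots[nk - ord + 1])
  splines::splineDesign(basis$knots, x, ord = ord)
}

t_loglik <- function(r, sigma, nu) {
  if (is.infinite(nu)) {
    sum(dnorm(r, sd = sigma, log = TRUE))
  } else {
    n <- length(r)
    n * (lgamma((nu + 1) / 2) - lgamma(nu / 2) - 0.5 * log(nu * pi) -
           log(sigma)) -
      (nu + 1) / 2 * sum(log1p(r^2 / (nu * sigma^2)))
  }
}

## one penalized scaled-t fit at fixed (lambda, nu): iteratively
## reweighted penalized least squares with EM updates for sigma
pspline_t_single <- function(X, y, pen, lambda, nu, beta0 = NULL,
                             max_iter = 200, tol = 1e-6) {
  n <- length(y)
  XtX_fun <- function(w) crossprod(X * w, X)
  beta <- beta0
  if (is.null(beta)) {
    beta <- solve(XtX_fun(rep(1, n)) + lambda * pen + 1e-10 * diag(ncol(X)),
                  crossprod(X, y))
  }
  r <- y - drop(X %*% beta)
  sigma <- max(sd(r), 1e-6)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    w <- if (is.infinite(nu)) rep(1, n) else
      (nu + 1) / (nu + (r / sigma)^2)
    A <- XtX_fun(w) + lambda * pen + 1e-10 * diag(ncol(X))
    beta_new <- solve(A, crossprod(X * w, y))
    delta <- max(abs(beta_new - beta))
    beta <- beta_new
    r <- y - drop(X %*% beta)
    sigma <- max(sqrt(mean(if (is.infinite(nu)) r^2 else
      (nu + 1) / (nu + (r / sigma)^2) * r^2)), 1e-8)
    if (delta < tol) { converged <- TRUE; break }
  }
  w <- if (is.infinite(nu)) rep(1, n) else (nu + 1) / (nu + (r / sigma)^2)
  A <- XtX_fun(w) + lambda * pen + 1e-10 * diag(ncol(X))
  edf <- sum(diag(solve(A, XtX_fun(w))))
  ll <- t_loglik(r, sigma, nu)
  sbc <- -2 * ll + log(n) * (edf + 2)
  list(beta = drop(beta), sigma = sigma, nu = nu, lambda = lambda,
       edf = edf, loglik = ll, sbc = sbc, converged = converged,
       residuals = r)
}

fit_one_stratum <- function(age, z, offsets = NULL, n_knots = 20,
                            degree = 3, lambda_grid = NULL,
                            nu_grid = c(3, 4, 5, 6, 8, 10, 15, 20, 30, Inf),
                            max_iter = 200, tol = 1e-6) {
  domain <- range(age)
  basis <- pspline_basis(domain, n_knots, degree)
  B <- eval_basis(basis, age)
  D <- diff(diag(basis$k), differences = 2)
  pen <- crossprod(D)
  X <- B
  n_off <- 0L
  off_levels <- NULL
  if (!is.null(offsets)) {
    f <- factor(offsets)
    if (nlevels(f) > 1) {
      Dm <- stats::model.matrix(~f)[, -1, drop = FALSE]
      off_levels <- levels(f)
      n_off <- ncol(Dm)
      X <- cbind(B, Dm)
      pen <- rbind(cbind(pen, matrix(0, basis$k, n_off)),
                   matrix(0, n_off, basis$k + n_off))
    }
  }
  if (is.null(lambda_grid)) {
    lambda_grid <- 10^seq(-2, 4, length.out = 40) * length(z) / 1000
  }

  scan_lambda <- function(nu) {
    best <- NULL
    beta0 <- NULL
    for (lam in lambda_grid) {
      fit <- pspline_t_single(X, z, pen, lam, nu, beta0 = beta0,
                              max_iter = max_iter, tol = tol)
      beta0 <- fit$beta
      if (is.null(best) || fit$sbc < best$sbc) best <- fit
    }
    best
  }

  ## stage 1: Gaussian scan to locate lambda; stage 2: profile nu there;
  ## stage 3: full lambda rescan at the chosen nu
  g <- scan_lambda(Inf)
  nu_fits <- lapply(nu_grid, function(nu) {
    pspline_t_single(X, z, pen, g$lambda, nu, beta0 = g$beta,
                     max_iter = max_iter, tol = tol)
  })
  sbcs <- vapply(nu_fits, `[[`, numeric(1), "sbc")
  nu_star <- nu_grid[which.min(sbcs)]
  fit <- if (is.infinite(nu_star)) g else scan_lambda(nu_star)
  if (!fit$converged) {
    stop(sprintf(
      "penalized t fit did not converge (lambda=%.3g, nu=%s, edf=%.1f)",
      fit$lambda, format(fit$nu), fit$edf))
  }
  structure(
    list(basis = basis, coef = fit$beta[seq_len(basis$k)],
         offset_coef = if (n_off > 0)
           fit$beta[basis$k + seq_len(n_off)] else NULL,
         offset_levels = off_levels,
         lambda = fit$lambda, lambda_grid = lambda_grid, edf = fit$edf,
         sigma = fit$sigma, nu = fit$nu, loglik = fit$loglik,
         sbc = fit$sbc, age_domain = domain, n = length(z),
         residuals = fit$residuals, ages = age),
    class = "z_curve_fit")
}

#' Fit population median z-score trajectories
#'
#' Fits the median weight-for-age z-score as a smooth function of age
#' with a penalized cubic B-spline (P-spline: second-order difference
#' penalty on the coefficients) and scaled-t (TF) errors, which keeps
#' the fitted location a median-like centre robust to heavy tails.
#' The smoothing parameter is chosen to minimise the Schwarz Bayes
#' Criterion, `SBC = -2 logLik + log(n) * (edf + 2)`, over a grid of
#' penalties; the t degrees of freedom are profiled over a grid
#' (including the Gaussian limit). Strata (e.g. groups or size
#' classes) can be fitted with separate smooths via `by`, or with a
#' shared smooth plus additive offsets via `offset_col`.
#'
#' @param records Data frame with an age column and a z-score column.
#' @param age_col,z_col Column names (defaults `"age_years"`, `"z"`).
#' @param by Optional column name: fit a separate smooth per level.
#' @param offset_col Optional column name: additive (unpenalized)
#'   level offsets on a shared smooth.
#' @param truncate_age Optional upper age limit applied before
#'   fitting (colony-style presets truncate at 1.15 years, where older
#'   data run thin).
#' @param n_knots Interior knots, equally spaced over the observed age
#'   range (default 20).
#' @param lambda_grid Penalty grid; default 40 log-spaced values
#'   (scaled with n).
#' @param nu_grid Candidate t degrees of freedom; `Inf` is the
#'   Gaussian limit.
#' @param min_n Minimum records per stratum (default 50); smaller
#'   strata are skipped with a warning.
#' @param max_iter,tol Inner-loop controls.
#' @return A `z_curve_fit` (single stratum) or a named list of them.
#' @export
fit_z_curve <- function(records, age_col = "age_years", z_col = "z",
                        by = NULL, offset_col = NULL, truncate_age = NULL,
                        n_knots = 20, lambda_grid = NULL,
                        nu_grid = c(3, 4, 5, 6, 8, 10, 15, 20, 30, Inf),
                        min_n = 50, max_iter = 200, tol = 1e-6) {
  records <- records[!is.na(records[[z_col]]) & !is.na(records[[age_col]]), ,
                     drop = FALSE]
  if (!is.null(truncate_age)) {
    records <- records[records[[age_col]] <= truncate_age, , drop = FALSE]
  }
  one <- function(sub, label) {
    if (nrow(sub) < min_n) {
      warning(sprintf("stratum %s has %d records (< %d); skipped",
                      label, nrow(sub), min_n))
      return(NULL)
    }
    fit <- fit_one_stratum(
      sub[[age_col]], sub[[z_col]],
      offsets = if (!is.null(offset_col)) sub[[offset_col]] else NULL,
      n_knots = n_knots, lambda_grid = lambda_grid, nu_grid = nu_grid,
      max_iter = max_iter, tol = tol)
    fit$group_label <- label
    fit
  }
  if (is.null(by)) {
    return(one(records, "pooled"))
  }
  levels <- unique(as.character(records[[by]]))
  fits <- lapply(levels, function(g) {
    one(records[records[[by]] == g, , drop = FALSE], g)
  })
  names(fits) <- levels
  fits[!vapply(fits, is.null, logical(1))]
}

#' @export
print.z_curve_fit <- function(x, ...) {
  cat(sprintf(
    "<z_curve_fit> %s: n=%d, edf=%.2f, sigma=%.3f, nu=%s, SBC=%.1f, ages [%.2f, %.2f]\n",
    x$group_label %||% "pooled", x$n, x$edf, x$sigma, format(x$nu),
    x$sbc, x$age_domain[1], x$age_domain[2]))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate a fitted median z curve
#'
#' Evaluates the fitted median z-score at the requested ages, plus the
#' companion centile scale `100 * pnorm(z)` (the centile of the
#' growth standard the median curve sits on). Ages outside the fitted
#' domain are an error.
#'
#' @param fit A `z_curve_fit`.
#' @param ages Ages in years.
#' @param offset_level Optional stratum level when the fit carries
#'   additive offsets (the reference level adds 0).
#' @return Tibble with `age_years`, `z_median`, `centile`.
#' @export
predict_median <- function(fit, ages, offset_level = NULL) {
  B <- eval_basis(fit$basis, ages)
  mu <- drop(B %*% fit$coef)
  if (!is.null(offset_level) && !is.null(fit$offset_coef)) {
    i <- match(offset_level, fit$offset_levels)
    if (is.na(i)) stop("unknown offset level: ", offset_level)
    if (i > 1) mu <- mu + fit$offset_coef[i - 1]
  }
  tibble::tibble(age_years = ages, z_median = mu,
                 centile = 100 * pnorm(mu))
}

#' Normalized quantile residuals of a z-curve fit
#'
#' Maps raw residuals through the fitted scaled-t distribution and the
#' standard normal quantile function, giving residuals that are
#' standard normal under a correctly specified model.
#'
#' @param residuals Raw residuals.
#' @param sigma,nu Fitted scale and t degrees of freedom (`Inf` =
#'   Gaussian).
#' @return Normalized quantile residuals.
#' @export
quantile_residuals <- function(residuals, sigma = 1, nu = Inf) {
  u <- if (is.infinite(nu)) pnorm(residuals / sigma) else
    pt(residuals / sigma, df = nu)
  qnorm(pmin(pmax(u, 1e-12), 1 - 1e-12))
}

#' Worm-plot series for residual diagnostics
#'
#' Builds detrended normal QQ series ("worms") of normalized quantile
#' residuals in age panels: per panel the ordered residuals minus the
#' corresponding normal quantiles, with a 95 percent pointwise
#' envelope. A flat worm inside the envelope indicates adequate fit;
#' a panel-wide slope signals misfit scale, curvature signals skewness.
#'
#' @param residuals Raw residuals.
#' @param age Ages, same length.
#' @param n_panels Number of age panels (split at age quantiles).
#' @param sigma,nu Fitted scale and degrees of freedom for the
#'   quantile-residual transform.
#' @param min_per_panel Minimum residuals per panel (default 20);
#'   panels are merged (with a warning) until satisfied.
#' @return Tibble with `panel`, `age_lo`, `age_hi`, `x` (normal
#'   quantile), `worm` (detrended residual), `envelope` (half-width).
#' @export
worm_plot_data <- function(residuals, age, n_panels = 4, sigma = 1,
                           nu = Inf, min_per_panel = 20) {
  n <- length(residuals)
  while (n_panels > 1 && n / n_panels < min_per_panel) {
    n_panels <- n_panels - 1
  }
  if (n < min_per_panel) warning("few residuals; single sparse panel")
  rq <- quantile_residuals(residuals, sigma, nu)
  br <- quantile(age, probs = seq(0, 1, length.out = n_panels + 1))
  br[1] <- br[1] - 1e-9
  panel <- cut(age, breaks = br, labels = FALSE)
  out <- lapply(seq_len(n_panels), function(p) {
    r <- sort(rq[panel == p])
    m <- length(r)
    if (m == 0) return(NULL)
    pr <- stats::ppoints(m)
    x <- qnorm(pr)
    se <- sqrt(pr * (1 - pr) / m) / dnorm(x)
    tibble::tibble(panel = p, age_lo = min(age[panel == p]),
                   age_hi = max(age[panel == p]), x = x, worm = r - x,
                   envelope = 1.96 * se)
  })
  dplyr::bind_rows(out)
}

## D'Agostino (1970) transformed skewness z-statistic
dagostino_skew_z <- function(x) {
  n <- length(x)
  m2 <- mean((x - mean(x))^2)
  g1 <- mean((x - mean(x))^3) / m2^1.5
  y <- g1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  b2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  w2 <- -1 + sqrt(2 * (b2 - 1))
  d <- 1 / sqrt(log(sqrt(w2)))
  a <- sqrt(2 / (w2 - 1))
  d * log(y / a + sqrt((y / a)^2 + 1))
}

## Anscombe & Glynn (1983) transformed kurtosis z-statistic
anscombe_kurt_z <- function(x) {
  n <- length(x)
  m2 <- mean((x - mean(x))^2)
  b2 <- mean((x - mean(x))^4) / m2^2
  eb2 <- 3 * (n - 1) / (n + 1)
  vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xx <- (b2 - eb2) / sqrt(vb2)
  sb <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  a <- 6 + 8 / sb * (2 / sb + sqrt(1 + 4 / sb^2))
  ((1 - 2 / (9 * a)) -
      ((1 - 2 / a) / (1 + xx * sqrt(2 / (a - 4))))^(1 / 3)) /
    sqrt(2 / (9 * a))
}

#' Q statistics for binned residual diagnostics
#'
#' Per age bin, computes z-statistics for the mean (exact), variance
#' (Wilson-Hilferty chi-square transform), skewness (D'Agostino) and
#' kurtosis (Anscombe-Glynn) of the normalized quantile residuals,
#' then aggregates each moment's statistics as `Q = sum(z_g^2)`,
#' referred to a chi-square distribution with one degree of freedom
#' per contributing bin (less `df_adjust` to account for parameters
#' estimated from the same data, default 0).
#'
#' @param residuals Raw residuals.
#' @param age Ages.
#' @param n_bins Number of age bins (quantile-based, default 4).
#' @param sigma,nu Quantile-residual transform parameters.
#' @param min_per_bin Bins below this size are dropped with a warning
#'   (default 10).
#' @param df_adjust Degrees-of-freedom reduction per moment.
#' @return List with `table` (tibble: `moment`, `Q`, `df`, `p`) and
#'   `bin_z` (tibble of per-bin z-statistics).
#' @export
q_statistics <- function(residuals, age, n_bins = 4, sigma = 1, nu = Inf,
                         min_per_bin = 10, df_adjust = 0) {
  rq <- quantile_residuals(residuals, sigma, nu)
  br <- unique(quantile(age, probs = seq(0, 1, length.out = n_bins + 1)))
  br[1] <- br[1] - 1e-9
  bin <- cut(age, breaks = br, labels = FALSE)
  zrows <- list()
  for (b in sort(unique(bin))) {
    r <- rq[bin == b]
    m <- length(r)
    if (m < min_per_bin) {
      warning(sprintf("age bin %d has %d residuals; dropped", b, m))
      next
    }
    s2 <- var(r)
    z2 <- ((s2)^(1 / 3) - (1 - 2 / (9 * (m - 1)))) /
      sqrt(2 / (9 * (m - 1)))
    zrows[[length(zrows) + 1]] <- tibble::tibble(
      bin = b, n = m,
      z_mean = sqrt(m) * mean(r),
      z_var = z2,
      z_skew = dagostino_skew_z(r),
      z_kurt = anscombe_kurt_z(r))
  }
  if (length(zrows) < 1) stop("no usable age bins")
  bz <- dplyr::bind_rows(zrows)
  g <- nrow(bz)
  mk <- function(zcol) {
    q <- sum(bz[[zcol]]^2)
    df <- max(g - df_adjust, 1)
    tibble::tibble(Q = q, df = df, p = pchisq(q, df, lower.tail = FALSE))
  }
  tab <- dplyr::bind_rows(
    cbind(moment = "mean", mk("z_mean")),
    cbind(moment = "variance", mk("z_var")),
    cbind(moment = "skewness", mk("z_skew")),
    cbind(moment = "kurtosis", mk("z_kurt")))
  list(table = tibble::as_tibble(tab), bin_z = bz)
}

#' Compare group mean z-scores with a random-intercept mixed model
#'
#' Fits `z ~ group + (1 | dog)` by REML (dog as a random factor, so
#' repeated visits of the same dog are not treated as independent) and
#' reports all pairwise group contrasts with Tukey-adjusted p-values
#' and adjusted 95 percent confidence intervals, using
#' Satterthwaite-approximated degrees of freedom.
#'
#' @param records Data frame with the response, a dog identifier and a
#'   group column.
#' @param group_col Grouping column name.
#' @param dog_col Dog identifier column (default `"dog_id"`).
#' @param z_col Response column (default `"z"`).
#' @param conf_level Confidence level (default 0.95).
#' @return List with `fit` (the lmer fit), `contrasts` (tibble:
#'   `contrast`, `estimate`, `se`, `df`, `lower`, `upper`, `p_adj`,
#'   `method`) and `variance` (tibble: `sigma_u`, `sigma_e`).
#' @export
mixed_model_compare <- function(records, group_col, dog_col = "dog_id",
                                z_col = "z", conf_level = 0.95) {
  dat <- data.frame(z = records[[z_col]],
                    group = factor(records[[group_col]]),
                    dog = factor(records[[dog_col]]))
  if (nlevels(dat$group) < 2) stop("need at least 2 groups")
  single_visit <- nlevels(dat$dog) == nrow(dat)
  if (single_visit) {
    ## one record per dog: the random intercept is unidentifiable and
    ## the model collapses to a one-way ANOVA
    warning("one record per dog; collapsing to one-way ANOVA with ",
            "Tukey contrasts")
    fit <- stats::lm(z ~ group, data = dat)
    emm <- emmeans::emmeans(fit, "group")
    method <- "tukey_anova"
    variance <- tibble::tibble(sigma_u = 0,
                               sigma_e = stats::sigma(fit))
  } else {
    fit <- lmerTest::lmer(z ~ group + (1 | dog), data = dat,
                          REML = TRUE)
    if (lme4::isSingular(fit, tol = 1e-5)) {
      warning("between-dog variance estimated at the boundary (0); ",
              "contrast df are conservative")
    }
    emm <- emmeans::emmeans(fit, "group", lmer.df = "satterthwaite",
                            lmerTest.limit = nrow(dat))
    method <- "tukey_lmm"
    vc <- as.data.frame(lme4::VarCorr(fit))
    variance <- tibble::tibble(
      sigma_u = vc$sdcor[vc$grp == "dog"],
      sigma_e = vc$sdcor[vc$grp == "Residual"])
  }
  prs <- emmeans::contrast(emm, method = "pairwise", adjust = "tukey")
  ci <- stats::confint(prs, level = conf_level)
  lo <- if (!is.null(ci$lower.CL)) ci$lower.CL else ci$asymp.LCL
  hi <- if (!is.null(ci$upper.CL)) ci$upper.CL else ci$asymp.UCL
  ps <- summary(prs)
  list(
    fit = fit,
    contrasts = tibble::tibble(
      contrast = as.character(ps$contrast),
      estimate = ps$estimate, se = ps$SE, df = ps$df,
      lower = lo, upper = hi,
      p_adj = ps$p.value, method = method),
    variance = variance)
}
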