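#' @keywords internal
"_PACKAGE"

## small deterministic string hash (polynomial, mod 2^31-1) used to
## stamp outputs with the configuration they came from
config_hash <- function(x) {
  s <- paste(deparse(x), collapse = "")
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

pipeline_defaults <- function() {
  list(mode = "clinic", chart_levels = c(0.004, 0.02, 0.09, 0.25, 0.50,
                                         0.75, 0.91, 0.98, 0.996),
       n_bins = 40, span = 0.5, tau_ind = 1.5, group_col = "group",
       truncate_age = NULL, subsample = NULL, seed = 20200923,
       min_n_fit = 50)
}

#' Run the full validation pipeline
#'
#' Orchestrates the analysis sequence over one cohort: cleaning
#' (eligibility, population and individual outliers, extreme
#' trajectories), z-scoring, per-dog centile-line crossing summaries
#' and their frequency table, the net-crossing ANOVA with Tukey
#' contrasts, penalized-spline median z trajectories per group with
#' worm-plot and Q-statistic diagnostics, and the random-intercept
#' mixed-model group comparison. A manifest records the seed and a
#' hash of the configuration so reruns are verifiable.
#'
#' @param config Named list. Required: `records` (record tibble or CSV
#'   path) and `standards` (standards list or CSV path). Optional:
#'   `breed_map`, `mode` (`"clinic"`/`"colony"`), `chart_levels`,
#'   `n_bins`, `span`, `tau_ind`, `group_col`, `truncate_age`,
#'   `subsample` (record count for the curve fit; requires `seed`),
#'   `seed`, `min_n_fit`.
#' @return A report bundle: list with `clean`, `cleaning_report`,
#'   `crossings`, `crossing_table`, `net_comparison`, `curve_fits`,
#'   `curves`, `diagnostics`, `mixed_comparison`, `manifest`.
#' @export
run_validation_pipeline <- function(config) {
  for (field in c("records", "standards")) {
    if (is.null(config[[field]])) {
      stop(sprintf("config is missing required field '%s'", field))
    }
  }
  cfg <- utils::modifyList(pipeline_defaults(), config)
  records <- cfg$records
  if (is.character(records)) {
    records <- tibble::as_tibble(
      utils::read.csv(records, stringsAsFactors = FALSE,
                      comment.char = "#"))
  }
  standards <- cfg$standards
  if (is.character(standards)) standards <- load_standards(standards)
  chart <- centile_chart(cfg$chart_levels)

  cleaned <- clean_dataset(records, standards, breed_map = cfg$breed_map,
                           mode = cfg$mode, n_bins = cfg$n_bins,
                           span = cfg$span, tau_ind = cfg$tau_ind,
                           chart = chart)
  clean <- cleaned$clean

  group_col <- if (!is.null(clean[[cfg$group_col]])) cfg$group_col else NULL
  crossings <- if (nrow(clean) > 0) {
    cohort_crossings(clean, chart, group_col = group_col)
  } else NULL
  crossing_table <- if (!is.null(crossings)) tabulate_crossings(crossings)
    else NULL
  n_groups <- if (!is.null(crossings))
    length(unique(stats::na.omit(crossings$group))) else 0
  net_cmp <- NULL
  if (n_groups >= 2) {
    net_cmp <- tryCatch(net_crossing_comparison(crossings),
                        error = function(e) {
                          warning("net-crossing comparison skipped: ",
                                  conditionMessage(e))
                          NULL
                        })
  }

  fit_data <- clean
  if (!is.null(cfg$subsample) && nrow(fit_data) > cfg$subsample) {
    if (is.null(config$seed)) stop("subsampling requires an explicit seed")
    set.seed(cfg$seed)
    fit_data <- fit_data[sample.int(nrow(fit_data), cfg$subsample), ,
                         drop = FALSE]
  }
  fits <- NULL
  curves <- NULL
  diagnostics <- NULL
  if (nrow(fit_data) >= cfg$min_n_fit) {
    by <- if (n_groups >= 2) group_col else NULL
    fits <- fit_z_curve(fit_data, by = by,
                        truncate_age = cfg$truncate_age,
                        min_n = cfg$min_n_fit)
    if (inherits(fits, "z_curve_fit")) fits <- list(pooled = fits)
    curves <- dplyr::bind_rows(lapply(names(fits), function(g) {
      f <- fits[[g]]
      ages <- seq(f$age_domain[1], f$age_domain[2], length.out = 50)
      cbind(group = g, predict_median(f, ages))
    }))
    diagnostics <- lapply(fits, function(f) {
      list(worm = worm_plot_data(f$residuals, f$ages, sigma = f$sigma,
                                 nu = f$nu),
           q = tryCatch(
             q_statistics(f$residuals, f$ages, sigma = f$sigma,
                          nu = f$nu)$table,
             error = function(e) NULL))
    })
  }

  mixed_cmp <- NULL
  if (n_groups >= 2 && !is.null(group_col)) {
    mixed_cmp <- tryCatch(
      mixed_model_compare(clean, group_col = group_col),
      error = function(e) {
        warning("mixed-model comparison skipped: ", conditionMessage(e))
        NULL
      })
  }

  cfg_for_hash <- cfg[setdiff(names(cfg), c("records", "standards",
                                            "breed_map"))]
  bundle <- list(
    clean = clean, cleaning_report = cleaned$report,
    crossings = crossings, crossing_table = crossing_table,
    net_comparison = net_cmp, curve_fits = fits, curves = curves,
    diagnostics = diagnostics, mixed_comparison = mixed_cmp,
    manifest = list(
      package_version = as.character(utils::packageVersion("pupgrowth")),
      seed = cfg$seed, config_hash = config_hash(cfg_for_hash),
      n_records_in = cleaned$report$counts$n_records_in,
      n_records_kept = cleaned$report$counts$n_records_kept,
      n_dogs_kept = cleaned$report$counts$n_dogs_kept))
  bundle
}

write_stamped_csv <- function(df, path, hash) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], signif, digits = 6)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# config_hash: %s", hash), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Write a pipeline report bundle to disk
#'
#' Emits CSV tables (6 significant digits, each stamped with the
#' configuration hash in a leading comment line) and JSON metadata:
#' cleaned records, cleaning report, crossing table
#' (`group,direction,bin,count,percent`), net-crossing and
#' mixed-model contrasts, predicted curves, fit metadata and
#' diagnostics, and the run manifest.
#'
#' @param bundle Output of [run_validation_pipeline()].
#' @param dir Output directory (created if missing).
#' @return Character vector of written paths, invisibly.
#' @export
write_report <- function(bundle, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  h <- bundle$manifest$config_hash
  paths <- character(0)
  emit_csv <- function(df, name) {
    if (is.null(df)) return()
    p <- file.path(dir, name)
    write_stamped_csv(as.data.frame(df), p, h)
    paths <<- c(paths, p)
  }
  emit_json <- function(x, name) {
    if (is.null(x)) return()
    p <- file.path(dir, name)
    jsonlite::write_json(c(list(config_hash = h), x), p,
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
    paths <<- c(paths, p)
  }
  emit_csv(bundle$clean, "clean.csv")
  emit_csv(bundle$crossing_table, "crossing_table.csv")
  emit_csv(bundle$curves, "curves.csv")
  if (!is.null(bundle$net_comparison)) {
    emit_csv(bundle$net_comparison$contrasts, "net_crossing_contrasts.csv")
  }
  if (!is.null(bundle$mixed_comparison)) {
    emit_csv(bundle$mixed_comparison$contrasts, "mixed_model_contrasts.csv")
  }
  emit_json(list(counts = bundle$cleaning_report$counts,
                 dog_exclusions = bundle$cleaning_report$dog_exclusions),
            "cleaning_report.json")
  if (!is.null(bundle$curve_fits)) {
    emit_json(lapply(bundle$curve_fits, function(f) {
      list(group = f$group_label, knots = f$basis$knots,
           degree = f$basis$degree, coefficients = f$coef,
           lambda = f$lambda, edf = f$edf, sigma = f$sigma, nu = f$nu,
           sbc = f$sbc, age_domain = f$age_domain, n = f$n)
    }), "fits.json")
  }
  if (!is.null(bundle$diagnostics)) {
    emit_json(lapply(bundle$diagnostics, function(d) {
      list(q_table = d$q, worm = d$worm)
    }), "diagnostics.json")
  }
  emit_json(bundle$manifest, "manifest.json")
  invisible(paths)
}
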