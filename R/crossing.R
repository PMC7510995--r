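#' Centile-line crossings of one growth trajectory
#'
#' Counts, from the first visit's z-score, the maximum number of
#' centile lines crossed in each direction at any later visit: with
#' starting z-score `z1`, the upward count is the largest number of
#' chart lines lying strictly between `z1` and a subsequent visit's z
#' above it, and the downward count is defined symmetrically. A visit
#' sitting exactly on a line has not crossed it. The total is the
#' larger of the two directional counts (the crossing count at the
#' most differential point away from the starting centile).
#'
#' @param z z-scores of one dog's kept visits, in age order.
#' @param chart A [centile_chart()].
#' @return Tibble with one row: `start_z`, `start_channel` (index of
#'   the inter-line channel containing the start, 0 = below the lowest
#'   line), `up`, `down`, `total`, `up_bin`, `down_bin`, `total_bin`
#'   (labels in `0`, `1`, `2`, `>2`), and `scorable`. Trajectories with
#'   fewer than 2 visits are reported unscorable with `NA` counts.
#' @export
crossing_summary <- function(z, chart = centile_chart()) {
  lines <- chart$z_lines
  if (length(z) < 2) {
    return(tibble::tibble(
      start_z = if (length(z) == 1) z else NA_real_,
      start_channel = if (length(z) == 1) sum(lines < z) else NA_integer_,
      up = NA_integer_, down = NA_integer_, total = NA_integer_,
      up_bin = NA_character_, down_bin = NA_character_,
      total_bin = NA_character_, scorable = FALSE))
  }
  z1 <- z[1]
  rest <- z[-1]
  up <- max(vapply(rest, function(zj) sum(lines > z1 & lines < zj),
                   integer(1)))
  down <- max(vapply(rest, function(zj) sum(lines < z1 & lines > zj),
                     integer(1)))
  tibble::tibble(
    start_z = z1, start_channel = sum(lines < z1),
    up = up, down = down, total = max(up, down),
    up_bin = crossing_bin(up), down_bin = crossing_bin(down),
    total_bin = crossing_bin(max(up, down)), scorable = TRUE)
}

crossing_bin <- function(n) {
  ifelse(is.na(n), NA_character_, ifelse(n > 2, ">2", as.character(n)))
}

#' Crossing summaries for a whole cohort
#'
#' Applies [crossing_summary()] per dog over a cleaned record table.
#'
#' @param records Data frame with `dog_id`, `age_years`, `z`, and
#'   optionally a grouping column.
#' @param chart A [centile_chart()].
#' @param group_col Optional column name whose per-dog (first) value is
#'   carried into the output as `group`.
#' @return Tibble, one row per dog.
#' @export
cohort_crossings <- function(records, chart = centile_chart(),
                             group_col = NULL) {
  dogs <- unique(records$dog_id)
  rows <- lapply(dogs, function(d) {
    sub <- records[records$dog_id == d, , drop = FALSE]
    sub <- sub[order(sub$age_years), , drop = FALSE]
    cs <- crossing_summary(sub$z, chart)
    cs$dog_id <- d
    cs$group <- if (!is.null(group_col)) as.character(sub[[group_col]][1])
      else NA_character_
    cs
  })
  out <- dplyr::bind_rows(rows)
  out[, c("dog_id", "group", setdiff(names(out), c("dog_id", "group")))]
}

#' Tabulate centile-line crossings by group
#'
#' Builds a crossing frequency table in the chart-reading bins
#' 0, 1, 2 and more-than-2 lines, separately for the total, upward and
#' downward counts, with percentages of each group's scorable dogs.
#'
#' @param summaries Output of [cohort_crossings()] (or any tibble with
#'   `group`, `up`, `down`, `total`, `scorable`).
#' @return Tibble with columns `group`, `direction`, `bin`, `count`,
#'   `percent`; counts over the four bins sum to the group's scorable
#'   n for each direction.
#' @export
tabulate_crossings <- function(summaries) {
  bins <- c("0", "1", "2", ">2")
  summaries <- summaries[summaries$scorable %in% TRUE, , drop = FALSE]
  groups <- unique(summaries$group)
  rows <- list()
  for (g in groups) {
    sub <- summaries[is.na(summaries$group) == is.na(g) &
                       (is.na(g) | summaries$group == g), , drop = FALSE]
    n <- nrow(sub)
    for (direction in c("total", "up", "down")) {
      lab <- crossing_bin(sub[[direction]])
      cnt <- vapply(bins, function(b) sum(lab == b), integer(1),
                    USE.NAMES = FALSE)
      rows[[length(rows) + 1]] <- tibble::tibble(
        group = g, direction = direction, bin = bins, count = cnt,
        percent = if (n > 0) 100 * cnt / n else rep(NA_real_, 4))
    }
  }
  dplyr::bind_rows(rows)
}

#' Compare net crossings across groups
#'
#' The per-dog statistic is the net crossing count d = up - down.
#' Group means of d are compared with a one-way ANOVA and all pairwise
#' Tukey honest-significant-difference contrasts; when several such
#' tables are analysed in one run, a family-level Bonferroni factor
#' can be applied on top of the Tukey adjustment.
#'
#' @param summaries Output of [cohort_crossings()] with `group` set.
#' @param bonferroni_families Number of analysis families tested in the
#'   same run (default 1: no extra correction).
#' @return List with `anova` (tibble: `F`, `df1`, `df2`, `p`) and
#'   `contrasts` (tibble: `contrast`, `estimate`, `lwr`, `upr`,
#'   `p_adj`).
#' @export
net_crossing_comparison <- function(summaries, bonferroni_families = 1) {
  summaries <- summaries[summaries$scorable %in% TRUE, , drop = FALSE]
  d <- summaries$up - summaries$down
  g <- factor(summaries$group)
  if (nlevels(g) < 2) stop("need at least 2 groups")
  if (any(table(g) < 2)) stop("every group needs at least 2 dogs")
  if (stats::var(d) == 0) {
    ## all-identical response: F undefined, report a null result
    lev <- levels(g)
    pairs <- utils::combn(lev, 2)
    return(list(
      anova = tibble::tibble(F = 0, df1 = nlevels(g) - 1,
                             df2 = length(d) - nlevels(g), p = 1),
      contrasts = tibble::tibble(
        contrast = paste(pairs[2, ], pairs[1, ], sep = "-"),
        estimate = 0, lwr = 0, upr = 0, p_adj = 1)))
  }
  fit <- stats::aov(d ~ g)
  an <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit)$g
  p_adj <- pmin(1, tk[, "p adj"] * bonferroni_families)
  list(
    anova = tibble::tibble(F = an[["F value"]][1], df1 = an[["Df"]][1],
                           df2 = an[["Df"]][2], p = an[["Pr(>F)"]][1]),
    contrasts = tibble::tibble(contrast = rownames(tk),
                               estimate = tk[, "diff"], lwr = tk[, "lwr"],
                               upr = tk[, "upr"], p_adj = p_adj))
}
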