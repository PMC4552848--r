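#' Group summaries as percent of Normal
#'
#' For one outcome at one week, divides each Disease group's mean by the
#' Normal group's mean (x100).  The SD is the group's own SD on the
#' normalised scale (the Normal mean is treated as a fixed denominator),
#' matching the convention of reporting a single SD per cell.
#'
#' @param table a `cohort_table`-shaped data.frame with `group`, `week` and
#'   the outcome column.
#' @param outcome outcome column name.
#' @param week week to summarise.
#' @return data.frame with `group`, `n`, `mean_pct`, `sd_pct`.
#' @export
percent_of_normal <- function(table, outcome, week = 28) {
  stopifnot(outcome %in% names(table))
  d <- table[table$week == week & !is.na(table[[outcome]]), ]
  if (!any(d$group == "Normal"))
    stop("Normal group is empty at the requested week")
  mu_n <- mean(d[[outcome]][d$group == "Normal"])
  if (mu_n == 0) stop("Normal group mean is zero; percentages undefined")
  groups <- levels(factor(d$group))
  out <- do.call(rbind, lapply(groups, function(g) {
    y <- d[[outcome]][d$group == g]
    data.frame(group = g, n = length(y),
               mean_pct = 100 * mean(y) / mu_n,
               sd_pct = 100 * stats::sd(y) / mu_n)
  }))
  attr(out, "outcome") <- outcome
  attr(out, "week") <- week
  out
}

# extract one (outcome, week) column as a per-animal vector
.animal_values <- function(table, name, week) {
  d <- table[table$week == week, c("animal", name)]
  stats::setNames(d[[name]], d$animal)
}

#' Deformity-outcome linear regression
#'
#' Ordinary least squares of one outcome on one predictor across animals
#' (closed form), with the zero-order Pearson coefficient, the coefficient
#' of determination, and a two-sided p-value from the exact t transform of
#' r with n-2 degrees of freedom.
#'
#' @param table a `cohort_table`-shaped data.frame.
#' @param predictor `c(name, week)`: column name and week of the predictor.
#' @param outcome `c(name, week)` for the outcome.
#' @param groups groups to include (default: pooled Disease animals).
#' @return object of class `deformity_regression` with `slope`,
#'   `intercept`, `pearson_r`, `r_squared`, `p_value`, `n`, `se_slope`.
#' @export
regress <- function(table, predictor, outcome,
                    groups = c("Moderate", "Severe")) {
  pn <- predictor[[1]]; pw <- as.numeric(predictor[[2]])
  on_ <- outcome[[1]]; ow <- as.numeric(outcome[[2]])
  keep <- table$animal[table$week == 28 & table$group %in% groups]
  x <- .animal_values(table[table$animal %in% keep, ], pn, pw)
  y <- .animal_values(table[table$animal %in% keep, ], on_, ow)
  common <- intersect(names(x)[!is.na(x)], names(y)[!is.na(y)])
  x <- x[common]; y <- y[common]
  n <- length(x)
  if (n < 3) stop("at least 3 complete predictor/outcome pairs are required")
  sxx <- sum((x - mean(x))^2)
  if (sxx == 0) stop("predictor has zero variance")
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  resid <- y - intercept - slope * x
  syy <- sum((y - mean(y))^2)
  r <- if (syy == 0) 0 else sxy / sqrt(sxx * syy)
  r2 <- r^2
  se_slope <- sqrt(sum(resid^2) / (n - 2) / sxx)
  tstat <- if (abs(r) < 1) r * sqrt((n - 2) / (1 - r2)) else Inf
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  structure(list(slope = slope, intercept = intercept, pearson_r = r,
                 r_squared = r2, p_value = p, n = n, se_slope = se_slope,
                 predictor = sprintf("%s@%gwk", pn, pw),
                 outcome = sprintf("%s@%gwk", on_, ow),
                 residual_ss = sum(resid^2)),
            class = "deformity_regression")
}

#' @export
print.deformity_regression <- function(x, ...) {
  cat(sprintf(
    "<deformity_regression> %s ~ %s: slope %.3g, r %.3f, R^2 %.3f, p %.2g (n=%d)\n",
    x$outcome, x$predictor, x$slope, x$pearson_r, x$r_squared, x$p_value, x$n))
  invisible(x)
}

#' Test of a regression slope against unity
#'
#' t-test of `slope == 1` using the OLS slope standard error; used to ask
#' whether deformity progresses faster than it started (slope above 1 from
#' 6 to 28 weeks).
#'
#' @param result a [regress()] result.
#' @return list with `statistic`, `p_value`, `df`.
#' @export
slope_vs_unity_test <- function(result) {
  stopifnot(inherits(result, "deformity_regression"))
  if (result$n <= 2) stop("slope test requires n > 2")
  if (result$se_slope == 0 || !is.finite(result$se_slope) ||
      result$residual_ss < 1e-24)
    stop("degenerate fit: zero residual variance")
  tstat <- (result$slope - 1) / result$se_slope
  list(statistic = tstat,
       p_value = 2 * stats::pt(-abs(tstat), df = result$n - 2),
       df = result$n - 2)
}

#' Deformity-outcome correlation matrix over the Disease pool
#'
#' Regresses every growth and functional outcome on the maximal deformity
#' angle at 6 and at 28 weeks over the pooled Disease animals, reporting
#' the coefficient of determination with the sign of the Pearson
#' correlation.
#'
#' @param table a `cohort_table`-shaped data.frame.
#' @param outcomes outcome column names (defaults to the full study set).
#' @return data.frame of class `table2` with one row per outcome:
#'   `r2_6wk`, `sign_6wk`, `p_6wk`, `r2_28wk`, `sign_28wk`, `p_28wk`.
#' @export
build_table2 <- function(table, outcomes = NULL) {
  if (is.null(outcomes))
    outcomes <- c("body_mass", "rl_vol_ratio", "tra",
                  "frc_total", "frc_left", "frc_right",
                  "tlc_total", "tlc_left", "tlc_right",
                  "ic_total", "ic_left", "ic_right",
                  "mass_total", "mass_left", "mass_right",
                  "ftv_right", "ftv_left",
                  "rac_total", "rac_left", "rac_right",
                  "fvc", "elastance")
  n_dis <- sum(table$week == 28 & table$group %in% c("Moderate", "Severe"))
  if (n_dis < 3) stop("at least 3 Disease animals are required")
  rows <- list()
  for (o in outcomes) {
    if (!o %in% names(table)) {
      message(sprintf("outcome %s missing from cohort table; skipped", o))
      next
    }
    fit6 <- tryCatch(regress(table, c("theta_m", 6), c(o, 28)),
                     error = function(e) NULL)
    fit28 <- tryCatch(regress(table, c("theta_m", 28), c(o, 28)),
                      error = function(e) NULL)
    if (is.null(fit6) || is.null(fit28)) {
      message(sprintf("outcome %s could not be regressed; skipped", o))
      next
    }
    rows[[o]] <- data.frame(
      outcome = o,
      r2_6wk = fit6$r_squared, sign_6wk = ifelse(fit6$pearson_r >= 0, "+", "-"),
      p_6wk = fit6$p_value,
      r2_28wk = fit28$r_squared,
      sign_28wk = ifelse(fit28$pearson_r >= 0, "+", "-"),
      p_28wk = fit28$p_value)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("table2", "data.frame")
  out
}

#' Percent-of-normal summary across all outcomes (Table 1 shape)
#'
#' @param table a `cohort_table`-shaped data.frame.
#' @param outcomes outcome column names.
#' @param week week to summarise.
#' @return data.frame with one row per outcome x Disease group.
#' @export
build_table1 <- function(table,
                         outcomes = c("mass_left", "mass_right",
                                      "frc_left", "frc_right",
                                      "tlc_left", "tlc_right",
                                      "ic_left", "ic_right",
                                      "ftv_left", "ftv_right",
                                      "rac_left", "rac_right"),
                         week = 28) {
  out <- do.call(rbind, lapply(outcomes, function(o) {
    p <- percent_of_normal(table, o, week)
    p <- p[p$group != "Normal", ]
    p$outcome <- o
    p
  }))
  rownames(out) <- NULL
  out[, c("outcome", "group", "n", "mean_pct", "sd_pct")]
}
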