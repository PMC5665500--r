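# shared guard for metric slices
check_slice <- function(data, need, fn) {
  if (!is.data.frame(data) || nrow(data) == 0) {
    abort(paste0(fn, "() needs a non-empty result slice"))
  }
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0(fn, "() needs column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  invisible(data)
}

#' Bias of a slice of simulated estimates
#'
#' Mean (and median) of estimated minus true prevalence over the slice, in
#' percentage points. The median is reported alongside because skewed
#' small-sample estimate distributions can carry a positive mean bias while
#' the median sits near zero.
#'
#' @param data Result rows (from [run_study()]) sharing one
#'   method/size/cutoff; needs columns `point` and `true_prev`.
#' @return One-row tibble: `mean_bias_pp`, `median_bias_pp`, `n_rows`.
#' @examples
#' bias(tibble::tibble(point = c(0.15, 0.11, 0.10), true_prev = 0.10))
#' @export
bias <- function(data) {
  check_slice(data, c("point", "true_prev"), "bias")
  d <- 100 * (data$point - data$true_prev)
  tibble(mean_bias_pp = mean(d), median_bias_pp = median(d),
         n_rows = length(d))
}

#' Precision of a slice of simulated estimates
#'
#' Mean half-width of the 95% confidence intervals,
#' `mean((ci_high - ci_low) / 2)`, in percentage points. Smaller is better.
#'
#' @param data Result rows with columns `ci_low` and `ci_high`.
#' @return One-row tibble: `precision_pp`, `n_rows`.
#' @export
precision <- function(data) {
  check_slice(data, c("ci_low", "ci_high"), "precision")
  hw <- 100 * abs(data$ci_high - data$ci_low) / 2
  tibble(precision_pp = mean(hw), n_rows = length(hw))
}

#' Coverage of a slice of simulated estimates
#'
#' Proportion of confidence intervals containing the true prevalence
#' (closed interval: a truth sitting exactly on an endpoint counts as
#' covered).
#'
#' @param data Result rows with columns `ci_low`, `ci_high`, `true_prev`.
#' @return One-row tibble: `coverage`, `n_rows`.
#' @export
coverage <- function(data) {
  check_slice(data, c("ci_low", "ci_high", "true_prev"), "coverage")
  hit <- data$ci_low <= data$true_prev & data$true_prev <= data$ci_high
  tibble(coverage = mean(hit), n_rows = length(hit))
}

#' Threshold classification performance
#'
#' For a programmatic decision threshold (e.g. GAM above 5%, 10% or 15%),
#' how often an estimator puts a survey on the correct side. `p_correct` is
#' the sensitivity reading: among rows whose true prevalence is at or above
#' the threshold, the proportion whose point estimate is too. Specificity
#' (truth below, estimate below) and unconditional accuracy are reported as
#' well, so either reading of "correct classification" is available.
#'
#' @param data Result rows with columns `point` and `true_prev`.
#' @param threshold Threshold in percent (5, 10 or 15 in routine use).
#' @return One-row tibble: `threshold`, `p_correct`, `specificity`,
#'   `accuracy`, `n_eligible`, `n_rows`. `p_correct` is `NA` when no row has
#'   truth at or above the threshold.
#' @examples
#' classify(tibble::tibble(point = c(0.07, 0.12, 0.02),
#'                         true_prev = c(0.06, 0.20, 0.03)), 5)
#' @export
classify <- function(data, threshold) {
  check_slice(data, c("point", "true_prev"), "classify")
  thr <- threshold / 100
  truth_hi <- data$true_prev >= thr
  est_hi <- data$point >= thr
  n_eligible <- sum(truth_hi)
  tibble(threshold = threshold,
         p_correct = if (n_eligible == 0) NA_real_
                     else mean(est_hi[truth_hi]),
         specificity = if (all(truth_hi)) NA_real_
                       else mean(!est_hi[!truth_hi]),
         accuracy = mean(truth_hi == est_hi),
         n_eligible = n_eligible,
         n_rows = nrow(data))
}

#' Metric grid over a simulation result table
#'
#' One row of bias / precision / coverage per group, the tabular layout used
#' to compare estimators across sample sizes. Rows with a non-missing
#' `error_code` are dropped (with a message) before computing.
#'
#' @param results A [run_study()] result table.
#' @param by Grouping columns (default method x cutoff x sample size). A
#'   GAM-prevalence category or region column can be added for stratified
#'   summaries.
#' @return A tibble with the `by` columns plus `mean_bias_pp`,
#'   `median_bias_pp`, `precision_pp`, `coverage`, `n_rows`.
#' @export
summarize_metrics <- function(results,
                              by = c("method", "cutoff_mm", "sample_size")) {
  check_slice(results, c("point", "true_prev", "ci_low", "ci_high"),
              "summarize_metrics")
  unknown <- setdiff(by, names(results))
  if (length(unknown) > 0) {
    abort(paste0("unknown group key(s): ", paste(unknown, collapse = ", ")))
  }
  if ("error_code" %in% names(results)) {
    n_err <- sum(!is.na(results$error_code))
    if (n_err > 0) {
      inform(paste0("dropping ", n_err, " row(s) with estimator errors"))
      results <- results[is.na(results$error_code), , drop = FALSE]
    }
  }
  if (nrow(results) == 0) abort("no error-free rows to summarise")
  results %>%
    group_by(across(all_of(by))) %>%
    summarise(
      mean_bias_pp = mean(100 * (.data$point - .data$true_prev)),
      median_bias_pp = median(100 * (.data$point - .data$true_prev)),
      precision_pp = mean(100 * abs(.data$ci_high - .data$ci_low) / 2),
      coverage = mean(.data$ci_low <= .data$true_prev &
                        .data$true_prev <= .data$ci_high),
      n_rows = dplyr::n(), .groups = "drop")
}

#' Classification grid over a simulation result table
#'
#' [classify()] applied per group and threshold; operate on GAM rows
#' (cutoff 125 mm) for the standard decision-threshold table.
#'
#' @param results A [run_study()] result table (typically filtered to one
#'   cutoff).
#' @param thresholds Percent thresholds (default 5, 10, 15).
#' @param by Grouping columns.
#' @return A tibble with the `by` columns plus the [classify()] columns.
#' @export
classification_table <- function(results, thresholds = c(5, 10, 15),
                                 by = c("method", "sample_size")) {
  check_slice(results, c("point", "true_prev"), "classification_table")
  if ("error_code" %in% names(results)) {
    results <- results[is.na(results$error_code), , drop = FALSE]
  }
  results %>%
    group_by(across(all_of(by))) %>%
    dplyr::group_modify(function(g, key) {
      purrr::map_dfr(thresholds, function(thr) classify(g, thr))
    }) %>%
    ungroup()
}

#' Per-survey mean bias table for the bias regression
#'
#' Aggregates a result table to one row per (population, sample size,
#' method): the mean GAM bias across replicates, carried with the survey
#' metadata and a GAM-prevalence category — the unit of analysis for
#' [bias_regression()].
#'
#' @param results A [run_study()] result table; GAM rows (cutoff 125 mm) are
#'   selected automatically when several cutoffs are present.
#' @return A tibble with `pop_id`, `method`, `sample_size`, metadata
#'   columns, `gam_category` and `bias_pp`.
#' @export
mean_bias_by_survey <- function(results) {
  check_slice(results, c("point", "true_prev", "pop_id", "method",
                         "sample_size"), "mean_bias_by_survey")
  if ("cutoff_mm" %in% names(results) &&
      length(unique(results$cutoff_mm)) > 1) {
    results <- results[results$cutoff_mm == .CUTOFF_GAM, , drop = FALSE]
  }
  if ("error_code" %in% names(results)) {
    results <- results[is.na(results$error_code), , drop = FALSE]
  }
  meta <- intersect(c("region", "livelihood", "residence", "date_period",
                      "design", "true_gam"), names(results))
  results %>%
    group_by(across(all_of(c("pop_id", "method", "sample_size", meta)))) %>%
    summarise(bias_pp = mean(100 * (.data$point - .data$true_prev)),
              .groups = "drop") %>%
    mutate(gam_category = gam_category(
      if ("true_gam" %in% meta) .data$true_gam else NA_real_))
}

#' GAM prevalence category
#'
#' The four programmatic bands used to stratify performance: `<5%`, `5-9%`,
#' `10-14%`, `>=15%`.
#'
#' @param p True GAM prevalence as a proportion.
#' @return A factor with `<5%` as reference level.
#' @export
gam_category <- function(p) {
  cut(100 * p, breaks = c(-Inf, 5, 10, 15, Inf),
      labels = c("<5%", "5-9%", "10-14%", ">=15%"), right = FALSE)
}

#' Linear regression of mean bias on survey characteristics
#'
#' Ordinary least squares of per-survey mean bias (percentage points) on
#' dummy-coded survey characteristics, to locate where an estimator's bias
#' comes from. Reference levels follow the conventional baselines:
#' East Africa, GAM `<5%`, agriculture, rural, sample size 25, before 2006,
#' simple random design.
#'
#' @param data A table from [mean_bias_by_survey()] (or any table with a
#'   `bias_pp` column and the predictors).
#' @param predictors Character vector of predictor columns; constant
#'   predictors are dropped with a warning.
#' @return A `bias_regression` object wrapping the `lm` fit; see
#'   [tidy.bias_regression()].
#' @export
bias_regression <- function(data,
                            predictors = c("region", "gam_category",
                                           "livelihood", "residence",
                                           "sample_size", "date_period",
                                           "design")) {
  check_slice(data, "bias_pp", "bias_regression")
  predictors <- intersect(predictors, names(data))
  if (length(predictors) == 0) abort("no predictor columns found in `data`")
  refs <- c(region = "east_africa", gam_category = "<5%",
            livelihood = "agriculture", residence = "rural",
            sample_size = "25", date_period = "before_2006",
            design = "simple_random")
  df <- data
  kept <- character(0)
  for (p in predictors) {
    v <- df[[p]]
    if (p == "sample_size") v <- as.character(v)
    f <- factor(v)
    if (nlevels(f) < 2) {
      warn(paste0("predictor '", p, "' is constant; dropped"))
      next
    }
    if (!is.na(refs[p]) && refs[p] %in% levels(f)) {
      f <- stats::relevel(f, ref = refs[[p]])
    }
    df[[p]] <- f
    kept <- c(kept, p)
  }
  if (length(kept) == 0) abort("all predictors constant; nothing to fit")
  fml <- stats::as.formula(paste("bias_pp ~", paste(kept, collapse = " + ")))
  fit <- lm(fml, data = df)
  if (any(is.na(coef(fit)))) {
    bad <- names(coef(fit))[is.na(coef(fit))]
    abort(paste0("singular design matrix; collinear term(s): ",
                 paste(bad, collapse = ", ")))
  }
  structure(list(fit = fit, predictors = kept,
                 reference_levels = refs[kept]),
            class = "bias_regression")
}

#' Tidy a bias regression
#'
#' @param x A `bias_regression`.
#' @param conf.level Confidence level for the coefficient intervals.
#' @param ... Unused.
#' @return A tibble with one row per predictor level (reference levels
#'   included, flagged with `reference = TRUE` and no coefficient):
#'   `term`, `level`, `estimate`, `conf.low`, `conf.high`, `p.value`,
#'   `reference`.
#' @export
tidy.bias_regression <- function(x, conf.level = 0.95, ...) {
  fit <- x$fit
  cf <- summary(fit)$coefficients
  ci <- suppressWarnings(confint(fit, level = conf.level))
  rows <- list()
  for (p in x$predictors) {
    lv <- levels(fit$model[[p]])
    for (l in lv) {
      nm <- paste0(p, l)
      if (nm %in% rownames(cf)) {
        rows[[length(rows) + 1L]] <- tibble(
          term = p, level = l, estimate = cf[nm, "Estimate"],
          conf.low = ci[nm, 1], conf.high = ci[nm, 2],
          p.value = cf[nm, "Pr(>|t|)"], reference = FALSE)
      } else {
        rows[[length(rows) + 1L]] <- tibble(
          term = p, level = l, estimate = NA_real_, conf.low = NA_real_,
          conf.high = NA_real_, p.value = NA_real_, reference = TRUE)
      }
    }
  }
  bind_rows(rows)
}

#' @describeIn tidy.bias_regression Model-level summary (R-squared, sigma,
#'   n) of the underlying `lm` fit.
#' @export
glance.bias_regression <- function(x, ...) {
  s <- summary(x$fit)
  tibble(r.squared = s$r.squared, adj.r.squared = s$adj.r.squared,
         sigma = s$sigma, nobs = length(s$residuals))
}

#' @export
print.bias_regression <- function(x, ...) {
  cat("<bias_regression> mean bias (pp) ~",
      paste(x$predictors, collapse = " + "), "\n")
  print(tidy(x), n = 30)
  invisible(x)
}
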