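test_that("bias is the mean (and median) estimated-minus-true, in pp", {
  expect_equal(bias(tibble::tibble(point = c(0.1, 0.2),
                                   true_prev = c(0.1, 0.2)))$mean_bias_pp, 0)
  b <- bias(tibble::tibble(point = c(0.12, 0.08), true_prev = 0.10))
  expect_equal(b$mean_bias_pp, 0)
  expect_equal(b$median_bias_pp, 0)
  b2 <- bias(tibble::tibble(point = c(0.15, 0.11, 0.10), true_prev = 0.10))
  expect_equal(b2$mean_bias_pp, 2, tolerance = 1e-10)
  expect_error(bias(tibble::tibble(point = numeric(0),
                                   true_prev = numeric(0))), "non-empty")
})

test_that("precision is the mean CI half-width in pp", {
  expect_equal(precision(tibble::tibble(ci_low = rep(0.05, 3),
                                        ci_high = rep(0.15, 3)))$precision_pp,
               5)
  expect_equal(precision(tibble::tibble(ci_low = 0.2,
                                        ci_high = 0.2))$precision_pp, 0)
  expect_equal(precision(tibble::tibble(ci_low = c(0, 0.1),
                                        ci_high = c(0.2, 0.2)))$precision_pp,
               7.5)
})

test_that("coverage counts closed-interval containment", {
  expect_equal(coverage(tibble::tibble(ci_low = 0, ci_high = 1,
                                       true_prev = c(0.1, 0.9)))$coverage, 1)
  expect_equal(coverage(tibble::tibble(ci_low = 0.5, ci_high = 0.6,
                                       true_prev = 0.1))$coverage, 0)
  # truth exactly on an endpoint counts as covered
  expect_equal(coverage(tibble::tibble(ci_low = 0, ci_high = 0.2,
                                       true_prev = 0))$coverage, 1)
  # coverage + non-coverage = 1 exactly
  set.seed(3)
  df <- tibble::tibble(ci_low = runif(50, 0, 0.4),
                       ci_high = runif(50, 0.4, 1),
                       true_prev = runif(50))
  hit <- coverage(df)$coverage
  miss <- mean(df$true_prev < df$ci_low | df$true_prev > df$ci_high)
  expect_identical(hit + miss, 1)
})

test_that("nominal-95% normal-mean CIs achieve nominal coverage", {
  # analytic CIs for a normal mean on 2,000 seeded SRS draws: the empirical
  # coverage of the coverage() metric must sit in the binomial MC band
  set.seed(5)
  n <- 50
  rows <- purrr::map_dfr(1:2000, function(i) {
    x <- rnorm(n, 0.3, 0.1)
    hw <- qnorm(0.975) * sd(x) / sqrt(n) * 1 # known-variance style interval
    tibble::tibble(point = mean(x), ci_low = mean(x) - hw,
                   ci_high = mean(x) + hw, true_prev = 0.3)
  })
  expect_gt(coverage(rows)$coverage, 0.93)
  expect_lt(coverage(rows)$coverage, 0.97)
})

test_that("classification follows the threshold rule", {
  all_right <- classify(tibble::tibble(point = 0.20, true_prev = 0.20), 15)
  expect_equal(all_right$p_correct, 1)
  all_wrong <- classify(tibble::tibble(point = rep(0.10, 4),
                                       true_prev = rep(0.20, 4)), 15)
  expect_equal(all_wrong$p_correct, 0)
  mixed <- classify(tibble::tibble(point = c(0.07, 0.12, 0.02),
                                   true_prev = c(0.06, 0.20, 0.03)), 5)
  expect_equal(mixed$n_eligible, 2)
  expect_equal(mixed$p_correct, 1) # both eligible estimates clear 5%
  expect_equal(mixed$specificity, 1)
  # and a genuinely half-right slice
  half <- classify(tibble::tibble(point = c(0.07, 0.04),
                                  true_prev = c(0.06, 0.20)), 5)
  expect_equal(half$n_eligible, 2)
  expect_equal(half$p_correct, 0.5)
  # no eligible rows: flagged, not invented
  none <- classify(tibble::tibble(point = 0.01, true_prev = 0.01), 15)
  expect_equal(none$n_eligible, 0)
  expect_true(is.na(none$p_correct))
})

test_that("summarize_metrics produces one row per group", {
  set.seed(7)
  res <- tidyr::expand_grid(method = c("a", "b"), sample_size = c(25, 100),
                            rep = 1:3) %>%
    dplyr::mutate(cutoff_mm = 125, true_prev = 0.2,
                  point = 0.2 + rnorm(dplyr::n(), 0, 0.02),
                  ci_low = point - 0.05, ci_high = point + 0.05,
                  error_code = NA_character_)
  m <- summarize_metrics(res, by = c("method", "sample_size"))
  expect_equal(nrow(m), 4)
  expect_true(all(m$n_rows == 3))
  # adding a second grouping key multiplies the rows
  res$region <- rep(c("asia", "caribbean"), length.out = nrow(res))
  m2 <- summarize_metrics(res, by = c("method", "sample_size", "region"))
  expect_equal(nrow(m2), 8)
  expect_error(summarize_metrics(res, by = "nope"), "unknown group key")
  # error rows are dropped before summarising
  res$error_code[1] <- "boom"
  expect_message(summarize_metrics(res, by = "method"), "dropping 1")
})

test_that("bias regression recovers exact planted effects", {
  # constant bias: every non-intercept coefficient is zero
  df <- tidyr::expand_grid(region = c("east_africa", "asia"),
                           sample_size = c(25, 50), i = 1:3) %>%
    dplyr::mutate(bias_pp = 1.25)
  fit <- bias_regression(df, predictors = c("region", "sample_size"))
  td <- suppressWarnings(tidy(fit))
  expect_equal(td$estimate[!td$reference], c(0, 0), tolerance = 1e-10)
  expect_true(all(td$reference[td$level %in% c("east_africa", "25")]))

  # noiseless two-group contrast: coefficient 0.5, zero-width CI
  df2 <- tibble::tibble(region = rep(c("east_africa", "asia"), each = 3),
                        bias_pp = rep(c(0, 0.5), each = 3))
  fit2 <- bias_regression(df2, predictors = "region")
  td2 <- suppressWarnings(tidy(fit2))
  est <- td2[td2$level == "asia", ]
  expect_equal(est$estimate, 0.5, tolerance = 1e-12)
  expect_equal(est$conf.high - est$conf.low, 0, tolerance = 1e-9)

  # constant predictors are dropped with a warning
  df3 <- dplyr::mutate(df2, residence = "rural")
  expect_warning(bias_regression(df3, predictors = c("region", "residence")),
                 "constant")
})

test_that("mean_bias_by_survey aggregates to the regression unit", {
  res <- tidyr::expand_grid(pop_id = c("p1", "p2"), method = "probit_II",
                            sample_size = c(25, 50), rep = 1:4) %>%
    dplyr::mutate(cutoff_mm = 125, region = "asia", true_gam = 0.08,
                  true_prev = 0.08, point = 0.08 + 0.01 * rep,
                  error_code = NA_character_)
  tab <- mean_bias_by_survey(res)
  expect_equal(nrow(tab), 4) # 2 pops x 2 sizes
  expect_equal(unique(tab$bias_pp), 2.5) # mean of 1,2,3,4 pp
  expect_equal(as.character(unique(tab$gam_category)), "5-9%")
})

test_that("glance and autoplot work on a bias regression", {
  set.seed(11)
  df <- tibble::tibble(
    region = sample(c("east_africa", "asia", "caribbean"), 120, TRUE),
    bias_pp = rnorm(120))
  fit <- bias_regression(df, predictors = "region")
  g <- glance(fit)
  expect_equal(g$nobs, 120)
  p <- autoplot(fit)
  expect_s3_class(p, "ggplot")
})
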