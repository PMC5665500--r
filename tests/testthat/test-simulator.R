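test_that("population_spec validates and lists every violation", {
  expect_s3_class(population_spec(seed = 1), "population_spec")
  err <- tryCatch(population_spec(n_clusters = 10, muac_sd_mm = -1,
                                  icc = 1.2),
                  error = function(e) conditionMessage(e))
  expect_match(err, "25 clusters")
  expect_match(err, "muac_sd_mm")
  expect_match(err, "icc")
})

test_that("generated populations recover the target mean and SD", {
  # SRS population of 10,000: mean within 3 SE, SD within chi-square band
  spec <- population_spec(n_clusters = 100, children_per_cluster = 100,
                          icc = 0, design = "simple_random", seed = 101)
  pop <- generate_population(spec)
  expect_equal(nrow(pop), 10000)
  expect_lt(abs(mean(pop$muac_mm) - 135), 3 * 12.5 / sqrt(10000))
  expect_lt(abs(sd(pop$muac_mm) - 12.5), 0.3)
})

test_that("generated populations recover the target ICC", {
  spec <- population_spec(n_clusters = 100, children_per_cluster = 100,
                          icc = 0.3, seed = 202)
  pop <- generate_population(spec)
  rho_hat <- muacprobit:::anova_icc(pop$muac_mm, pop$cluster_id)
  expect_lt(abs(rho_hat - 0.3), 0.05)
})

test_that("skewed populations keep the target moments and skew direction", {
  spec <- population_spec(n_clusters = 100, children_per_cluster = 100,
                          icc = 0, design = "simple_random",
                          skewness = 4, seed = 303)
  pop <- generate_population(spec)
  expect_lt(abs(mean(pop$muac_mm) - 135), 3 * 12.5 / sqrt(10000))
  expect_lt(abs(sd(pop$muac_mm) - 12.5), 0.3)
  m3 <- mean((pop$muac_mm - mean(pop$muac_mm))^3) / sd(pop$muac_mm)^3
  expect_gt(m3, 0.2) # right-skewed as requested
})

test_that("unskewed populations pass a normality check in most seeded runs", {
  pvals <- vapply(1:20, function(i) {
    pop <- generate_population(population_spec(
      n_clusters = 25, children_per_cluster = 40, icc = 0,
      design = "simple_random", seed = 400 + i))
    stats::shapiro.test(pop$muac_mm)$p.value
  }, numeric(1))
  expect_gte(mean(pvals > 0.01), 0.95)
})

test_that("population generation is deterministic in the spec seed", {
  a <- generate_population(population_spec(seed = 7))
  b <- generate_population(population_spec(seed = 7))
  expect_identical(a, b)
})

test_that("clustered subsamples have exact size and cluster structure", {
  pop <- generate_population(population_spec(seed = 17))
  # 200 = 25 clusters x 8 children
  s200 <- subsample_clustered(pop, 200, seed = 1)
  expect_equal(nrow(s200), 200)
  expect_equal(dplyr::n_distinct(s200$cluster_id), 25)
  expect_true(all(table(s200$cluster_id) == 8))
  # m = 1: 25 distinct clusters, one child each
  s25 <- subsample_clustered(pop, 25, seed = 2)
  expect_equal(nrow(s25), 25)
  expect_equal(dplyr::n_distinct(s25$cluster_id), 25)
  # records are drawn without replacement (continuous MUAC: ties a.s. absent)
  expect_equal(anyDuplicated(s200$muac_mm), 0)
  expect_error(subsample_clustered(pop, 30), "multiple")
  few <- make_survey(rnorm(40, 135, 12), cluster = rep(1:10, each = 4))
  expect_error(subsample_clustered(few, 25), "at least 25")
})

test_that("clusters holding exactly m children are taken whole", {
  pop <- generate_population(population_spec(
    n_clusters = 25, children_per_cluster = 8, seed = 23))
  s <- subsample_clustered(pop, 200, seed = 3)
  expect_equal(sort(s$muac_mm), sort(pop$muac_mm))
})

test_that("short clusters are topped up to an exact sample size", {
  # 40 clusters of 6 children: m = 8 cannot be met within a cluster
  pop <- generate_population(population_spec(
    n_clusters = 40, children_per_cluster = 6, seed = 29))
  s <- subsample_clustered(pop, 200, seed = 4)
  expect_equal(nrow(s), 200)
  expect_equal(anyDuplicated(s[c("cluster_id", "muac_mm")]), 0)
})

test_that("simple-random subsampling is without replacement and seeded", {
  pop <- generate_population(population_spec(
    n_clusters = 40, children_per_cluster = 25, icc = 0,
    design = "simple_random", seed = 31))
  s <- subsample_srs(pop, 25, seed = 5)
  expect_equal(nrow(s), 25)
  expect_equal(anyDuplicated(s$muac_mm), 0)
  expect_identical(s, subsample_srs(pop, 25, seed = 5))
  # boundary: target_n = n gives a permutation of the survey
  all_of_it <- subsample_srs(pop, nrow(pop), seed = 6)
  expect_equal(sort(all_of_it$muac_mm), sort(pop$muac_mm))
  expect_error(subsample_srs(pop, nrow(pop) + 1), "need")
})

test_that("large SRS subsamples converge to the source prevalence", {
  pop <- generate_population(population_spec(
    n_clusters = 100, children_per_cluster = 100, icc = 0,
    design = "simple_random", seed = 37))
  p_true <- true_prevalence(pop, 125)
  s <- subsample_srs(pop, 2000, seed = 7)
  tol <- 3 * sqrt(p_true * (1 - p_true) / 2000)
  expect_lt(abs(true_prevalence(s, 125) - p_true), tol)
})

test_that("run_study yields the expected row grid and presses on after errors", {
  pops <- list(generate_population(population_spec(seed = 41,
                                                   survey_id = "p1")),
               generate_population(population_spec(seed = 43,
                                                   survey_id = "p2")))
  des <- simulation_design(sample_sizes = c(25, 50), reps = 3)
  res <- run_study(pops, design = des, methods = c("classic", "probit_II"),
                   cutoffs = 125, n_boot = 50, seed = 47)
  # 2 populations x 2 sizes x 3 reps x 2 methods x 1 cutoff
  expect_equal(nrow(res), 24)
  expect_equal(attr(res, "n_subsamples"), 12)
  expect_true(all(is.na(res$error_code)))

  # identical seed -> identical table
  res2 <- run_study(pops, design = des, methods = c("classic", "probit_II"),
                    cutoffs = 125, n_boot = 50, seed = 47)
  expect_identical(res, res2)

  # a constant-MUAC population breaks the sample-SD PROBIT but not the run
  flat <- make_survey(rep(130, 200), cluster = rep(1:25, each = 8),
                      survey_id = "flat")
  res3 <- run_study(list(flat), design = simulation_design(
    sample_sizes = 25, reps = 2),
    methods = c("classic", "probit_II"), cutoffs = 125, n_boot = 50,
    seed = 53)
  expect_equal(nrow(res3), 4)
  expect_true(all(!is.na(res3$error_code[res3$method == "probit_II"])))
  expect_true(all(is.na(res3$error_code[res3$method == "classic"])))

  expect_error(run_study(pops, design = des, methods = "probit_I",
                         cutoffs = 125, seed = 1), "sd_ref")
})
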