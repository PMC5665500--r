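#' Run the package's synthetic calibration benchmark
#'
#' A canned Monte-Carlo experiment for checking estimator calibration under
#' controlled conditions: `n_populations` synthetic cluster-survey
#' populations (default spec: 30 clusters x 27 children, mean MUAC 135 mm,
#' SD 12.5 mm, ICC 0.05, regions and other metadata assigned round-robin),
#' an SD reference built from those same populations, and a full
#' [run_study()] over the design grid at both the SAM (115 mm) and GAM
#' (125 mm) cutoffs. Feed the `results` element to [summarize_metrics()]
#' and [classification_table()] to compare the estimators.
#'
#' With the defaults (50 populations x 100 replicates x 8 sizes, 500
#' bootstrap replications) the run takes a few minutes on one core.
#'
#' @param n_populations Number of synthetic populations.
#' @param design A [simulation_design()].
#' @param methods Estimators to run.
#' @param n_boot Bootstrap replications per PROBIT estimate (default 500;
#'   raise to 2000 for production-grade CIs).
#' @param seed Master integer seed.
#' @param spec_overrides Named list overriding [population_spec()] arguments
#'   shared by every population (e.g. `list(icc = 0.1)`).
#' @param progress Passed to [run_study()].
#' @return A list: `populations` (list of survey tibbles), `sd_ref`
#'   (the built `sd_reference`), `results` (the [run_study()] table).
#' @examples
#' \donttest{
#' bm <- benchmark_study(n_populations = 3,
#'                       design = simulation_design(sample_sizes = c(25, 100),
#'                                                  reps = 5),
#'                       n_boot = 100, seed = 1)
#' summarize_metrics(bm$results)
#' }
#' @export
benchmark_study <- function(n_populations = 50,
                            design = simulation_design(),
                            methods = c("classic", "probit_I", "probit_II"),
                            n_boot = 500, seed = 1,
                            spec_overrides = list(), progress = FALSE) {
  populations <- lapply(seq_len(n_populations), function(i) {
    args <- modifyList(list(
      region = .REGIONS[(i - 1) %% length(.REGIONS) + 1],
      livelihood = .LIVELIHOODS[(i - 1) %% length(.LIVELIHOODS) + 1],
      residence = .RESIDENCES[(i - 1) %% length(.RESIDENCES) + 1],
      date_period = .DATE_PERIODS[(i - 1) %% length(.DATE_PERIODS) + 1],
      survey_id = sprintf("pop%03d", i),
      seed = substream_seed(seed, 11, i)), spec_overrides)
    generate_population(do.call(population_spec, args))
  })
  sd_ref <- build_sd_reference(populations, n_boot = 2000,
                               seed = substream_seed(seed, 12))
  results <- run_study(populations, design = design, methods = methods,
                       sd_ref = sd_ref, cutoffs = c(.CUTOFF_SAM, .CUTOFF_GAM),
                       n_boot = n_boot, seed = substream_seed(seed, 13),
                       progress = progress)
  list(populations = populations, sd_ref = sd_ref, results = results)
}
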