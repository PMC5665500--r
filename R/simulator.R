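#' Specify a synthetic survey population
#'
#' A population is a single large survey treated as population-representative
#' truth, emulating the kind of field survey (two-stage cluster or simple
#' random, roughly normal MUAC) from which small samples are drawn. Defaults
#' describe a typical cluster survey: 30 clusters of 27 children (~810
#' children, the size of an average field survey), mean MUAC 135 mm, SD
#' 12.5 mm, mild clustering (ICC 0.05).
#'
#' @param n_clusters Number of clusters (>= 25 for clustered designs).
#' @param children_per_cluster Children measured per cluster.
#' @param muac_mean_mm Target marginal mean MUAC (mm).
#' @param muac_sd_mm Target marginal SD of MUAC (mm), > 0.
#' @param icc Intracluster correlation of MUAC, in `[0, 1)`.
#' @param skewness Slant parameter of a skew-normal child-level residual
#'   (0 = normal). The residual is moment-corrected so the marginal mean and
#'   SD still match `muac_mean_mm` / `muac_sd_mm`.
#' @param design `"clustered"` (default) or `"simple_random"` (then the
#'   population has `n_clusters * children_per_cluster` unclustered records
#'   and `icc` must be 0).
#' @param region,livelihood,residence,date_period Survey metadata labels.
#' @param survey_id Identifier for the generated survey.
#' @param seed Integer seed making the population reproducible.
#' @return A `population_spec` list, validated.
#' @examples
#' spec <- population_spec(seed = 1)
#' pop <- generate_population(spec)
#' true_prevalence(pop, 125)
#' @export
population_spec <- function(n_clusters = 30, children_per_cluster = 27,
                            muac_mean_mm = 135, muac_sd_mm = 12.5,
                            icc = 0.05, skewness = 0,
                            design = c("clustered", "simple_random"),
                            region = "east_africa",
                            livelihood = "agriculture",
                            residence = "rural",
                            date_period = "after_2006",
                            survey_id = "pop1", seed = NULL) {
  design <- match.arg(design)
  spec <- list(n_clusters = as.integer(n_clusters),
               children_per_cluster = as.integer(children_per_cluster),
               muac_mean_mm = muac_mean_mm, muac_sd_mm = muac_sd_mm,
               icc = icc, skewness = skewness, design = design,
               region = region, livelihood = livelihood,
               residence = residence, date_period = date_period,
               survey_id = survey_id, seed = seed)
  problems <- character(0)
  if (spec$n_clusters < 1) problems <- c(problems, "n_clusters must be >= 1")
  if (design == "clustered" && spec$n_clusters < 25) {
    problems <- c(problems, "clustered populations need >= 25 clusters")
  }
  if (spec$children_per_cluster < 1) {
    problems <- c(problems, "children_per_cluster must be >= 1")
  }
  if (!is.numeric(muac_sd_mm) || muac_sd_mm <= 0) {
    problems <- c(problems, "muac_sd_mm must be > 0")
  }
  if (!is.numeric(icc) || icc < 0 || icc >= 1) {
    problems <- c(problems, "icc must lie in [0, 1)")
  }
  if (design == "simple_random" && icc != 0) {
    problems <- c(problems, "simple_random populations must have icc = 0")
  }
  if (length(problems) > 0) {
    abort(paste0("invalid population spec:\n  - ",
                 paste(problems, collapse = "\n  - ")))
  }
  structure(spec, class = "population_spec")
}

# standardized skew-normal draws (mean 0, SD 1) with slant alpha
rskewnorm_std <- function(n, alpha) {
  if (alpha == 0) return(rnorm(n))
  delta <- alpha / sqrt(1 + alpha^2)
  z <- delta * abs(rnorm(n)) + sqrt(1 - delta^2) * rnorm(n)
  mu <- delta * sqrt(2 / pi)
  (z - mu) / sqrt(1 - delta^2 * 2 / pi)
}

#' Generate a synthetic survey population
#'
#' Draws cluster effects from `Normal(0, sd^2 * icc)` and child-level
#' residuals (normal, or moment-corrected skew-normal when
#' `spec$skewness != 0`) with variance `sd^2 * (1 - icc)`, so the marginal
#' mean and SD match the spec. The output is an ordinary survey tibble and
#' can be fed to every estimator or subsampler.
#'
#' @param spec A [population_spec()].
#' @return A survey tibble with columns `survey_id`, `cluster_id`,
#'   `muac_mm`, `design`, `region`, `livelihood`, `residence`, `date_period`.
#' @export
generate_population <- function(spec) {
  if (!inherits(spec, "population_spec")) {
    abort("`spec` must be created with population_spec()")
  }
  with_seed(spec$seed, {
    k <- spec$n_clusters
    m <- spec$children_per_cluster
    n <- k * m
    sd_b <- spec$muac_sd_mm * sqrt(spec$icc)
    sd_w <- spec$muac_sd_mm * sqrt(1 - spec$icc)
    if (spec$design == "clustered") {
      cl_eff <- rnorm(k, 0, sd_b)
      muac <- spec$muac_mean_mm + rep(cl_eff, each = m) +
        sd_w * rskewnorm_std(n, spec$skewness)
      cluster_id <- rep(sprintf("c%03d", seq_len(k)), each = m)
    } else {
      muac <- spec$muac_mean_mm + spec$muac_sd_mm *
        rskewnorm_std(n, spec$skewness)
      cluster_id <- NA_character_
    }
    tibble(survey_id = spec$survey_id, cluster_id = cluster_id,
           muac_mm = muac, design = spec$design, region = spec$region,
           livelihood = spec$livelihood, residence = spec$residence,
           date_period = spec$date_period)
  })
}

#' Small-sample simulation design
#'
#' The grid of simulated-survey sizes and replicate counts. The default
#' mirrors the standard small-survey experiment: 100 simulated surveys at
#' each of the eight sizes 25, 50, ..., 200, each clustered subsample
#' spreading its records over 25 clusters (1 to 8 children per cluster).
#'
#' @param sample_sizes Integer vector of target sample sizes; each must be a
#'   multiple of `n_clusters_sub`.
#' @param reps Simulated surveys per (population, size) cell.
#' @param n_clusters_sub Clusters per clustered subsample.
#' @return A validated `simulation_design` list.
#' @export
simulation_design <- function(sample_sizes = c(25, 50, 75, 100, 125, 150,
                                               175, 200),
                              reps = 100, n_clusters_sub = 25) {
  if (any(sample_sizes %% n_clusters_sub != 0)) {
    abort("every sample size must be a multiple of n_clusters_sub")
  }
  if (reps < 1) abort("reps must be >= 1")
  structure(list(sample_sizes = as.integer(sample_sizes),
                 reps = as.integer(reps),
                 n_clusters_sub = as.integer(n_clusters_sub)),
            class = "simulation_design")
}

#' Draw a clustered small-sample survey from a source survey
#'
#' Emulates the two-stage structure of a real cluster survey:
#' `n_clusters_sub` clusters are sampled without replacement, then
#' `m = target_n / n_clusters_sub` children are sampled without replacement
#' within each. A selected cluster holding fewer than `m` children
#' contributes all of them and the shortfall is filled from additionally
#' drawn spare clusters, so the sample size is always exact.
#'
#' @param src A clustered survey tibble with at least `n_clusters_sub`
#'   clusters.
#' @param target_n Target sample size, a multiple of `n_clusters_sub`.
#' @param n_clusters_sub Clusters to draw (default 25).
#' @param seed Optional integer seed.
#' @return A survey tibble of exactly `target_n` rows, `design` set to
#'   `"clustered"`.
#' @export
subsample_clustered <- function(src, target_n, n_clusters_sub = 25,
                                seed = NULL) {
  check_survey(src, require = c("muac_mm", "cluster_id"))
  if (target_n %% n_clusters_sub != 0) {
    abort("target_n must be a multiple of n_clusters_sub")
  }
  cl <- as.character(src$cluster_id)
  clusters <- unique(cl)
  if (length(clusters) < n_clusters_sub) {
    abort(paste0("source survey has ", length(clusters),
                 " clusters; need at least ", n_clusters_sub))
  }
  m <- target_n %/% n_clusters_sub
  with_seed(seed, {
    idx_by_cluster <- split(seq_len(nrow(src)), cl)
    order_all <- sample(clusters) # first n_clusters_sub chosen, rest spare
    chosen <- order_all[seq_len(n_clusters_sub)]
    spare <- order_all[-seq_len(n_clusters_sub)]
    take <- integer(0)
    for (c_id in chosen) {
      rows <- idx_by_cluster[[c_id]]
      take <- c(take, if (length(rows) <= m) rows
                else rows[sample.int(length(rows), m)])
    }
    # top up from spare clusters if any chosen cluster ran short
    for (c_id in spare) {
      deficit <- target_n - length(take)
      if (deficit <= 0) break
      rows <- idx_by_cluster[[c_id]]
      take <- c(take, if (length(rows) <= deficit) rows
                else rows[sample.int(length(rows), deficit)])
    }
    if (length(take) < target_n) {
      abort("source survey too small to reach target_n")
    }
    out <- src[take, , drop = FALSE]
    out$design <- "clustered"
    out
  })
}

#' Draw a simple-random small-sample survey from a source survey
#'
#' @param src A survey tibble with at least `target_n` rows.
#' @param target_n Records to sample without replacement.
#' @param seed Optional integer seed.
#' @return A survey tibble of `target_n` rows, `design` set to
#'   `"simple_random"` and cluster ids cleared.
#' @export
subsample_srs <- function(src, target_n, seed = NULL) {
  check_survey(src)
  if (nrow(src) < target_n) {
    abort(paste0("source survey has ", nrow(src), " records; need ",
                 target_n))
  }
  with_seed(seed, {
    out <- src[sample.int(nrow(src), target_n), , drop = FALSE]
    out$design <- "simple_random"
    if ("cluster_id" %in% names(out)) out$cluster_id <- NA_character_
    out
  })
}

#' Run a small-sample simulation study
#'
#' For every population x sample size x replicate, draws one subsample
#' (clustered or simple-random, matching the source design) and produces one
#' prevalence estimate per requested method per cutoff. Estimator failures
#' (e.g. degenerate zero-SD samples) are recorded per row in `error_code`
#' and the run continues. Each cell gets its own RNG substream derived from
#' `seed` with [substream_seed()], so any cell can be reproduced in
#' isolation.
#'
#' @param populations A list of survey tibbles (or one tibble split on
#'   `survey_id`), each treated as a population with known truth.
#' @param design A [simulation_design()].
#' @param methods Subset of `c("classic", "probit_I", "probit_II")`.
#' @param sd_ref An `sd_reference`; required when `"probit_I"` is requested.
#' @param cutoffs MUAC cutoffs in mm (default SAM 115 and GAM 125).
#' @param n_boot Bootstrap replications per PROBIT estimate.
#' @param seed Master integer seed (required for reproducibility).
#' @param progress Emit a message every 1000 subsamples.
#' @return A tibble with one row per (population, size, rep, method, cutoff):
#'   `pop_id`, metadata columns, `true_gam`, `true_sam`, `true_prev`,
#'   `sample_size`, `rep`, `method`, `cutoff_mm`, `point`, `ci_low`,
#'   `ci_high`, `se_z`, `error_code`.
#' @export
run_study <- function(populations, design = simulation_design(),
                      methods = c("classic", "probit_I", "probit_II"),
                      sd_ref = NULL, cutoffs = c(115, 125), n_boot = 2000,
                      seed = 1, progress = FALSE) {
  if (is.data.frame(populations)) {
    populations <- split(populations, populations$survey_id)
  }
  methods <- match.arg(methods, c("classic", "probit_I", "probit_II"),
                       several.ok = TRUE)
  if ("probit_I" %in% methods && is.null(sd_ref)) {
    abort("method probit_I requires `sd_ref` (see build_sd_reference())")
  }
  if (!inherits(design, "simulation_design")) {
    abort("`design` must come from simulation_design()")
  }
  n_pop <- length(populations)
  n_cells <- n_pop * length(design$sample_sizes) * design$reps
  n_rows <- n_cells * length(methods) * length(cutoffs)

  # preallocated result columns, filled by row index
  pop_id <- region <- livelihood <- residence <- date_period <-
    src_design <- method_v <- error_code <- character(n_rows)
  true_gam <- true_sam <- true_prev <- point <- ci_low <- ci_high <-
    se_z <- rep(NA_real_, n_rows)
  sample_size <- rep_v <- cutoff_v <- rep(NA_integer_, n_rows)

  meta_of <- function(pop, col) {
    if (col %in% names(pop)) as.character(pop[[col]][1]) else NA_character_
  }

  row <- 0L
  done <- 0L
  for (ip in seq_len(n_pop)) {
    pop <- populations[[ip]]
    check_survey(pop)
    p_design <- survey_design(pop)
    p_meta <- vapply(c("region", "livelihood", "residence", "date_period"),
                     function(cc) meta_of(pop, cc), character(1))
    t_gam <- true_prevalence(pop, .CUTOFF_GAM)
    t_sam <- true_prevalence(pop, .CUTOFF_SAM)
    truths <- vapply(cutoffs, function(cc) true_prevalence(pop, cc),
                     numeric(1))
    p_id <- meta_of(pop, "survey_id")
    if (is.na(p_id)) p_id <- paste0("pop", ip)
    for (is_ in seq_along(design$sample_sizes)) {
      sz <- design$sample_sizes[is_]
      for (ir in seq_len(design$reps)) {
        sub_seed <- substream_seed(seed, ip, is_, ir, 1)
        smp <- if (p_design == "clustered") {
          subsample_clustered(pop, sz, design$n_clusters_sub, seed = sub_seed)
        } else {
          subsample_srs(pop, sz, seed = sub_seed)
        }
        for (im in seq_along(methods)) {
          for (ic in seq_along(cutoffs)) {
            row <- row + 1L
            pop_id[row] <- p_id
            region[row] <- p_meta[["region"]]
            livelihood[row] <- p_meta[["livelihood"]]
            residence[row] <- p_meta[["residence"]]
            date_period[row] <- p_meta[["date_period"]]
            src_design[row] <- p_design
            true_gam[row] <- t_gam
            true_sam[row] <- t_sam
            true_prev[row] <- truths[ic]
            sample_size[row] <- sz
            rep_v[row] <- ir
            method_v[row] <- methods[im]
            cutoff_v[row] <- cutoffs[ic]
            est_seed <- substream_seed(seed, ip, is_, ir, 2, im, ic)
            est <- tryCatch(
              switch(methods[im],
                     classic = classic_estimate(smp, cutoffs[ic]),
                     probit_I = probit_I_estimate(smp, sd_ref, cutoffs[ic],
                                                  n_boot = n_boot,
                                                  seed = est_seed),
                     probit_II = probit_II_estimate(smp, cutoffs[ic],
                                                    n_boot = n_boot,
                                                    seed = est_seed)),
              error = function(e) conditionMessage(e))
            if (inherits(est, "prevalence_estimate")) {
              point[row] <- est$point
              ci_low[row] <- est$ci_low
              ci_high[row] <- est$ci_high
              se_z[row] <- est$se_z
              error_code[row] <- NA_character_
            } else {
              error_code[row] <- est
            }
          }
        }
        done <- done + 1L
        if (progress && done %% 1000L == 0L) {
          inform(paste0("run_study: ", done, "/", n_cells, " subsamples"))
        }
      }
    }
  }
  out <- tibble(pop_id = pop_id, region = region, livelihood = livelihood,
                residence = residence, date_period = date_period,
                design = src_design, true_gam = true_gam,
                true_sam = true_sam, true_prev = true_prev,
                sample_size = sample_size, rep = rep_v, method = method_v,
                cutoff_mm = as.numeric(cutoff_v), point = point,
                ci_low = ci_low, ci_high = ci_high, se_z = se_z,
                error_code = error_code)
  attr(out, "n_subsamples") <- n_cells
  out
}
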