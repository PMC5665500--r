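#' Sample standard deviation of MUAC in a survey
#'
#' @param data A survey tibble with a `muac_mm` column and at least two
#'   non-missing values.
#' @return Sample SD (divisor n - 1) in mm. A zero SD is returned as-is;
#'   downstream estimators reject it.
#' @examples
#' survey_sd(tibble::tibble(muac_mm = c(120, 130)))
#' @export
survey_sd <- function(data) {
  check_survey(data)
  x <- data$muac_mm[!is.na(data$muac_mm)]
  if (length(x) < 2) abort("survey_sd needs at least 2 non-missing records")
  sd(x)
}

#' Effective sample size of a survey
#'
#' `n / DEFF` where `DEFF = 1 + (mean cluster size - 1) * rho` and `rho` is
#' the one-way ANOVA intracluster correlation of MUAC (clusters as groups),
#' floored at zero. Simple-random surveys have `DEFF = 1` by definition.
#' Used to weight surveys when pooling their MUAC SDs: a heavily clustered
#' survey carries less information about the population SD than its raw
#' size suggests.
#'
#' @param data A survey tibble with `muac_mm` and, for clustered surveys,
#'   `cluster_id`.
#' @return Positive real, at most `nrow(data)`.
#' @examples
#' s <- tibble::tibble(muac_mm = rnorm(200, 135, 12), design = "simple_random")
#' effective_sample_size(s)
#' @export
effective_sample_size <- function(data) {
  check_survey(data)
  keep <- !is.na(data$muac_mm)
  data <- data[keep, , drop = FALSE]
  n <- nrow(data)
  if (n == 0) abort("empty dataset")
  if (survey_design(data) == "simple_random") return(as.numeric(n))
  check_survey(data, require = c("muac_mm", "cluster_id"))
  cl <- as.character(data$cluster_id)
  if (any(is.na(cl))) abort("clustered survey has records with missing cluster_id")
  k <- length(unique(cl))
  if (k < 2) abort("clustered survey needs at least 2 clusters")
  rho <- max(0, anova_icc(data$muac_mm, cl))
  m_bar <- n / k
  n / (1 + (m_bar - 1) * rho)
}

# one-way ANOVA intracluster correlation (may be negative; caller floors)
anova_icc <- function(x, cluster) {
  f <- factor(cluster)
  k <- nlevels(f)
  n <- length(x)
  nj <- tabulate(f)
  means <- tapply(x, f, mean)
  grand <- mean(x)
  ssb <- sum(nj * (means - grand)^2)
  ssw <- sum((x - means[as.integer(f)])^2)
  msb <- ssb / (k - 1)
  msw <- ssw / (n - k)
  # ANOVA estimator cluster-size constant for unbalanced designs
  m0 <- (n - sum(nj^2) / n) / (k - 1)
  if (msw == 0 && msb == 0) return(0)
  (msb - msw) / (msb + (m0 - 1) * msw)
}

new_sd_reference <- function(entries, n_boot = NA_integer_) {
  means <- entries %>%
    group_by(.data$region) %>%
    summarise(mean_sd_mm = sum(.data$sd_mm * .data$weight) / sum(.data$weight),
              n_surveys = dplyr::n(), .groups = "drop")
  structure(list(entries = entries, means = means, n_boot = n_boot),
            class = "sd_reference")
}

#' Build a regional MUAC-SD reference from prior surveys
#'
#' The external-SD PROBIT estimator ([probit_I_estimate()]) parameterises the
#' MUAC distribution with an SD taken from surveys done previously in the
#' same region. This builds that reference: each contributing survey's
#' sample SD is weighted by its effective sample size, surveys are stratified
#' by region (regional stratification keeps the SD spread small), and within
#' each region whole surveys are resampled with replacement, with probability
#' proportional to weight, `n_boot` times; the regional mean SD is the mean
#' over replications of the replicate-mean SD. The (SD, weight) pairs are
#' kept for later per-replicate draws ([draw_sd()]).
#'
#' @param surveys A list of survey tibbles, or a single tibble covering
#'   several surveys distinguished by `survey_id`. Each survey needs a
#'   `region` column.
#' @param n_boot Bootstrap replications per region (default 2000).
#' @param seed Optional integer seed for the bootstrap.
#' @return An `sd_reference` object; see also [default_sd_reference()],
#'   [draw_sd()], [write_sd_reference()].
#' @examples
#' surveys <- lapply(1:3, function(i) tibble::tibble(
#'   survey_id = paste0("s", i), muac_mm = rnorm(300, 135, 11 + i),
#'   region = "east_africa", design = "simple_random"))
#' ref <- build_sd_reference(surveys, n_boot = 200, seed = 1)
#' tidy(ref)
#' @export
build_sd_reference <- function(surveys, n_boot = 2000, seed = NULL) {
  if (is.data.frame(surveys)) {
    check_survey(surveys, require = c("muac_mm", "survey_id", "region"))
    surveys <- split(surveys, surveys$survey_id)
  }
  if (length(surveys) == 0) abort("no surveys supplied")
  entries <- purrr::map_dfr(surveys, function(s) {
    check_survey(s, require = c("muac_mm", "region"))
    sdv <- survey_sd(s)
    if (sdv <= 0) {
      warn(paste0("survey with zero MUAC SD dropped from the reference"))
      return(NULL)
    }
    tibble(region = as.character(s$region[1]),
           sd_mm = sdv,
           weight = effective_sample_size(s),
           survey_id = if ("survey_id" %in% names(s))
             as.character(s$survey_id[1]) else NA_character_)
  })
  if (nrow(entries) == 0) abort("no usable surveys (all zero-SD)")
  if (is.factor(entries$region)) entries$region <- as.character(entries$region)

  boot_means <- with_seed(seed, {
    entries %>%
      group_by(.data$region) %>%
      dplyr::group_modify(function(g, key) {
        ns <- nrow(g)
        p <- g$weight / sum(g$weight)
        reps <- vapply(seq_len(n_boot), function(b) {
          mean(g$sd_mm[sample.int(ns, ns, replace = TRUE, prob = p)])
        }, numeric(1))
        tibble(mean_sd_mm = mean(reps))
      }) %>%
      ungroup()
  })
  ref <- new_sd_reference(entries, n_boot = as.integer(n_boot))
  # replace analytic weighted means with the bootstrap means
  ref$means <- ref$means %>%
    select(-"mean_sd_mm") %>%
    dplyr::left_join(boot_means, by = "region") %>%
    select("region", "mean_sd_mm", "n_surveys")
  ref
}

#' Built-in regional MUAC-SD reference
#'
#' Regional mean MUAC SDs published from a large multi-country compilation of
#' anthropometric surveys: 12.3 mm (East Africa), 12.8 mm (West Africa),
#' 13.0 mm (Central and South Africa), 12.8 mm (Caribbean), 12.0 mm (Asia).
#' The underlying survey-level SD distribution is not publicly available, so
#' by default each region is a point mass at its mean; `spread_mm > 0`
#' replaces the point mass with a 9-point normal-weighted grid spanning
#' about two `spread_mm` either side of the mean, for users who want
#' per-replicate SD variation without a prior-survey corpus.
#'
#' @param spread_mm Non-negative dispersion (mm) around each regional mean;
#'   0 (default) keeps the point mass.
#' @return An `sd_reference` object.
#' @examples
#' tidy(default_sd_reference())
#' @export
default_sd_reference <- function(spread_mm = 0) {
  means <- c(east_africa = 12.3, west_africa = 12.8,
             central_south_africa = 13.0, caribbean = 12.8, asia = 12.0)
  entries <- purrr::map_dfr(names(means), function(r) {
    if (spread_mm > 0) {
      grid <- seq(-2, 2, length.out = 9)
      tibble(region = r, sd_mm = means[[r]] + grid * spread_mm,
             weight = stats::dnorm(grid), survey_id = NA_character_)
    } else {
      tibble(region = r, sd_mm = means[[r]], weight = 1,
             survey_id = NA_character_)
    }
  })
  new_sd_reference(entries)
}

#' Draw MUAC SDs from a regional reference
#'
#' Samples from the empirical distribution of prior-survey SDs in a region,
#' with probability proportional to each survey's weight. Used once per
#' bootstrap replicate by [probit_I_estimate()].
#'
#' @param ref An `sd_reference`.
#' @param region Region name present in `ref`.
#' @param n Number of draws.
#' @param seed Optional integer seed.
#' @return Numeric vector of `n` SDs (mm).
#' @export
draw_sd <- function(ref, region, n = 1, seed = NULL) {
  stopifnot(inherits(ref, "sd_reference"))
  e <- ref$entries[ref$entries$region == region, , drop = FALSE]
  if (nrow(e) == 0) {
    abort(paste0("region '", region, "' absent from the SD reference (has: ",
                 paste(unique(ref$entries$region), collapse = ", "), ")"))
  }
  if (nrow(e) == 1) return(rep(e$sd_mm, n))
  with_seed(seed,
            e$sd_mm[sample.int(nrow(e), n, replace = TRUE,
                               prob = e$weight / sum(e$weight))])
}

# regional mean SD, with a clear error for absent regions
ref_mean_sd <- function(ref, region) {
  stopifnot(inherits(ref, "sd_reference"))
  i <- match(region, ref$means$region)
  if (is.na(i)) {
    abort(paste0("region '", region, "' absent from the SD reference"))
  }
  ref$means$mean_sd_mm[i]
}

#' @export
print.sd_reference <- function(x, ...) {
  cat("<sd_reference>", nrow(x$means), "region(s),",
      nrow(x$entries), "survey entries\n")
  print(x$means)
  invisible(x)
}

#' @describeIn build_sd_reference One row per region: `region`,
#'   `mean_sd_mm`, `n_surveys`.
#' @param x An `sd_reference`.
#' @param ... Unused.
#' @export
tidy.sd_reference <- function(x, ...) {
  x$means
}

#' Serialize / restore an SD reference as JSON
#'
#' Layout: `{region: {mean_sd_mm, entries: [[sd_mm, weight], ...]}}`.
#'
#' @param ref An `sd_reference`.
#' @param path File path for the JSON document.
#' @return `write_sd_reference()` returns `path` invisibly;
#'   `read_sd_reference()` returns an `sd_reference`.
#' @export
write_sd_reference <- function(ref, path) {
  stopifnot(inherits(ref, "sd_reference"))
  obj <- lapply(seq_len(nrow(ref$means)), function(i) {
    r <- ref$means$region[i]
    e <- ref$entries[ref$entries$region == r, , drop = FALSE]
    list(mean_sd_mm = ref$means$mean_sd_mm[i],
         entries = lapply(seq_len(nrow(e)),
                          function(j) c(e$sd_mm[j], e$weight[j])))
  })
  names(obj) <- ref$means$region
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_sd_reference
#' @export
read_sd_reference <- function(path) {
  obj <- jsonlite::read_json(path)
  entries <- purrr::map_dfr(names(obj), function(r) {
    purrr::map_dfr(obj[[r]]$entries, function(e) {
      tibble(region = r, sd_mm = as.numeric(e[[1]]),
             weight = as.numeric(e[[2]]), survey_id = NA_character_)
    })
  })
  ref <- new_sd_reference(entries)
  ref$means$mean_sd_mm <-
    unname(vapply(ref$means$region,
                  function(r) as.numeric(obj[[r]]$mean_sd_mm), numeric(1)))
  ref
}
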