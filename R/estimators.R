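#' Normal-model (PROBIT) prevalence below a cutoff
#'
#' Treats MUAC as normally distributed with the given mean and SD and returns
#' the cumulative probability below the case-defining cutoff,
#' `pnorm((cutoff - mean) / sd)`. This is the point estimate shared by both
#' PROBIT estimators; they differ only in where the SD comes from.
#'
#' @param mean_muac_mm Mean MUAC (mm).
#' @param sd_mm MUAC SD (mm), strictly positive.
#' @param cutoff_mm Case-defining cutoff (mm).
#' @return Prevalence as a proportion in `(0, 1)`. Vectorised over all three
#'   arguments.
#' @examples
#' probit_point(135, 12, 125)
#' @export
probit_point <- function(mean_muac_mm, sd_mm, cutoff_mm) {
  if (any(!is.finite(sd_mm)) || any(sd_mm <= 0)) {
    abort("degenerate sample: MUAC SD must be strictly positive")
  }
  pnorm((cutoff_mm - mean_muac_mm) / sd_mm)
}

new_prevalence_estimate <- function(method, cutoff_mm, point, ci_low, ci_high,
                                    n, mean_muac_mm = NA_real_,
                                    sd_used_mm = NA_real_, se_z = NA_real_,
                                    conf = 0.95) {
  structure(list(method = method, cutoff_mm = cutoff_mm, point = point,
                 ci_low = ci_low, ci_high = ci_high, n = n,
                 mean_muac_mm = mean_muac_mm, sd_used_mm = sd_used_mm,
                 se_z = se_z, conf = conf),
            class = "prevalence_estimate")
}

#' @export
print.prevalence_estimate <- function(x, ...) {
  cat(sprintf("<prevalence_estimate> %s, MUAC < %g mm\n", x$method,
              x$cutoff_mm))
  cat(sprintf("  %.1f%%  (%.0f%% CI %.1f%% - %.1f%%), n = %d\n",
              100 * x$point, 100 * x$conf, 100 * x$ci_low, 100 * x$ci_high,
              x$n))
  invisible(x)
}

#' Tidy a prevalence estimate
#'
#' @param x A `prevalence_estimate`.
#' @param ... Unused.
#' @return A one-row tibble with columns `method`, `cutoff_mm`, `point`,
#'   `ci_low`, `ci_high`, `n`, `mean_muac_mm`, `sd_used_mm`, `se_z`.
#' @export
tidy.prevalence_estimate <- function(x, ...) {
  tibble(method = x$method, cutoff_mm = x$cutoff_mm, point = x$point,
         ci_low = x$ci_low, ci_high = x$ci_high, n = x$n,
         mean_muac_mm = x$mean_muac_mm, sd_used_mm = x$sd_used_mm,
         se_z = x$se_z)
}

#' @describeIn tidy.prevalence_estimate One-row tibble of settings
#'   (`method`, `cutoff_mm`, `conf`, `n`).
#' @export
glance.prevalence_estimate <- function(x, ...) {
  tibble(method = x$method, cutoff_mm = x$cutoff_mm, conf = x$conf, n = x$n)
}

#' Classic design-based prevalence estimate
#'
#' Sample proportion of children below the cutoff, with a Wald confidence
#' interval. For clustered samples the standard error comes from the
#' between-cluster variability of the proportion (Taylor-linearised form,
#' which for k equal-size clusters reduces to
#' `SE^2 = sum((p_j - p)^2) / (k (k - 1))`); simple-random samples use the
#' binomial `sqrt(p (1 - p) / n)`. The interval is truncated to `[0, 1]`.
#'
#' @param data A survey tibble (sample) with `muac_mm` and, for clustered
#'   designs, `cluster_id`.
#' @param cutoff_mm Case-defining cutoff (mm).
#' @param conf Confidence level (default 0.95).
#' @return A `prevalence_estimate`.
#' @examples
#' s <- tibble::tibble(muac_mm = c(110, 130, 120, 140),
#'                     design = "simple_random")
#' classic_estimate(s, 125)
#' @export
classic_estimate <- function(data, cutoff_mm, conf = 0.95) {
  check_survey(data)
  x <- data$muac_mm
  if (anyNA(x)) {
    keep <- !is.na(x)
    data <- data[keep, , drop = FALSE]
    x <- x[keep]
  }
  n <- length(x)
  if (n == 0) abort("empty sample")
  y <- as.numeric(x < cutoff_mm)
  p <- mean(y)
  if (survey_design(data) == "clustered") {
    cl <- factor(data$cluster_id)
    k <- nlevels(cl)
    if (k < 2) abort("clustered sample needs at least 2 clusters")
    yj <- rowsum(y, cl)[, 1]
    nj <- tabulate(cl)
    se <- sqrt(k / (k - 1) * sum((yj - p * nj)^2) / n^2)
  } else {
    se <- sqrt(p * (1 - p) / n)
  }
  zq <- qnorm(1 - (1 - conf) / 2)
  new_prevalence_estimate("classic", cutoff_mm, p,
                          max(0, p - zq * se), min(1, p + zq * se),
                          n, mean_muac_mm = mean(x), conf = conf)
}

# ---- bootstrap core ---------------------------------------------------------

# replicate (mean, SD) pairs from a cluster bootstrap: resample k clusters
# with replacement, pooled moments from per-cluster sufficient statistics
boot_moments_clustered <- function(x, cluster, n_rep) {
  f <- factor(cluster)
  k <- nlevels(f)
  nj <- tabulate(f)
  sj <- rowsum(x, f)[, 1]
  qj <- rowsum(x^2, f)[, 1]
  idx <- matrix(sample.int(k, k * n_rep, replace = TRUE), k, n_rep)
  nb <- colSums(matrix(nj[idx], k))
  sb <- colSums(matrix(sj[idx], k))
  qb <- colSums(matrix(qj[idx], k))
  mb <- sb / nb
  vb <- (qb - sb^2 / nb) / (nb - 1)
  list(mean = mb, sd = sqrt(pmax(vb, 0)))
}

# replicate (mean, SD) pairs from an ordinary bootstrap of records
boot_moments_srs <- function(x, n_rep) {
  n <- length(x)
  idx <- matrix(sample.int(n, n * n_rep, replace = TRUE), n, n_rep)
  xm <- matrix(x[idx], n)
  sb <- colSums(xm)
  qb <- colSums(xm^2)
  mb <- sb / n
  vb <- (qb - sb^2 / n) / (n - 1)
  list(mean = mb, sd = sqrt(pmax(vb, 0)))
}

#' Bootstrap confidence interval for a PROBIT prevalence
#'
#' Resamples the sample `n_boot` times (whole clusters with replacement for
#' clustered samples, records for simple-random samples) and forms one
#' Z-score `z_b = (cutoff - mean_b) / sd_b` per replicate. The SD entering
#' each replicate follows `sd_draw`: `NULL` recomputes the SD on the
#' resample (sample-SD PROBIT), a function `f(n)` supplies `n` external
#' draws (reference-SD PROBIT), a single number holds the SD fixed. The
#' standard error of the replicate Z-scores gives a normal-theory interval
#' on the Z scale, back-transformed through the normal CDF:
#' `CI = pnorm(z_hat -/+ z_crit * se_z)`.
#'
#' Replicates with zero SD are redrawn and counted; if more than 10% of
#' `n_boot` need redrawing the sample is treated as degenerate and an error
#' is raised.
#'
#' @param data A survey tibble (sample).
#' @param cutoff_mm Case-defining cutoff (mm).
#' @param point_sd SD (mm) used for the point Z-score `z_hat`.
#' @param sd_draw `NULL`, a function, or a single number; see Details.
#' @param n_boot Bootstrap replications (default 2000).
#' @param conf Confidence level.
#' @param seed Optional integer seed.
#' @return A list with `ci_low`, `ci_high`, `se_z`, `z_hat`, `n_redraws`.
#' @export
probit_bootstrap_ci <- function(data, cutoff_mm, point_sd, sd_draw = NULL,
                                n_boot = 2000, conf = 0.95, seed = NULL) {
  check_survey(data)
  if (n_boot < 2) abort("n_boot must be at least 2")
  x <- data$muac_mm[!is.na(data$muac_mm)]
  clustered <- survey_design(data) == "clustered"
  cl <- if (clustered) as.character(data$cluster_id)[!is.na(data$muac_mm)]
  if (clustered && length(unique(cl)) < 2) {
    abort("cluster bootstrap needs at least 2 clusters")
  }
  if (!is.finite(point_sd) || point_sd <= 0) {
    abort("degenerate sample: MUAC SD must be strictly positive")
  }

  with_seed(seed, {
    draw_reps <- function(nr) {
      mo <- if (clustered) boot_moments_clustered(x, cl, nr)
            else boot_moments_srs(x, nr)
      sd_b <- if (is.null(sd_draw)) {
        mo$sd
      } else if (is.function(sd_draw)) {
        sd_draw(nr)
      } else {
        rep(as.numeric(sd_draw), nr)
      }
      (cutoff_mm - mo$mean) / sd_b
    }
    zb <- draw_reps(n_boot)
    n_redraws <- 0L
    for (round in 1:10) {
      bad <- !is.finite(zb)
      if (!any(bad)) break
      n_redraws <- n_redraws + sum(bad)
      if (n_redraws > 0.1 * n_boot) {
        abort("degenerate sample: >10% of bootstrap replicates had zero MUAC SD")
      }
      zb[bad] <- draw_reps(sum(bad))
    }
    if (any(!is.finite(zb))) {
      abort("degenerate sample: zero-SD bootstrap replicates persisted")
    }
    se_z <- sd(zb)
    z_hat <- (cutoff_mm - mean(x)) / point_sd
    zq <- qnorm(1 - (1 - conf) / 2)
    list(ci_low = pnorm(z_hat - zq * se_z),
         ci_high = pnorm(z_hat + zq * se_z),
         se_z = se_z, z_hat = z_hat, n_redraws = n_redraws)
  })
}

#' PROBIT prevalence estimate with an external (reference) SD
#'
#' The point estimate is `pnorm((cutoff - sample mean) / regional mean SD)`,
#' with the SD taken from a reference of prior surveys in the sample's
#' region ([build_sd_reference()], [default_sd_reference()]). The CI comes
#' from [probit_bootstrap_ci()] with, per replicate, the sample mean
#' recomputed on a (cluster) bootstrap resample and the SD drawn from the
#' reference's empirical SD distribution for the region.
#'
#' @param data A survey tibble (sample).
#' @param ref An `sd_reference` covering the sample's region.
#' @param cutoff_mm Case-defining cutoff (mm).
#' @param n_boot Bootstrap replications (default 2000).
#' @param seed Optional integer seed.
#' @param conf Confidence level.
#' @param region Region name; defaults to the sample's `region` column.
#' @return A `prevalence_estimate`.
#' @export
probit_I_estimate <- function(data, ref, cutoff_mm, n_boot = 2000,
                              seed = NULL, conf = 0.95, region = NULL) {
  check_survey(data)
  if (is.null(region)) {
    if (!"region" %in% names(data) || nrow(data) == 0) {
      abort("sample has no `region` column; pass `region =` explicitly")
    }
    region <- as.character(data$region[1])
  }
  sd_ref <- ref_mean_sd(ref, region)
  e <- ref$entries[ref$entries$region == region, , drop = FALSE]
  sd_fun <- if (nrow(e) == 1) {
    e$sd_mm # constant draw
  } else {
    pr <- e$weight / sum(e$weight)
    function(nr) e$sd_mm[sample.int(nrow(e), nr, replace = TRUE, prob = pr)]
  }
  x <- data$muac_mm[!is.na(data$muac_mm)]
  if (length(x) == 0) abort("empty sample")
  ci <- probit_bootstrap_ci(data, cutoff_mm, point_sd = sd_ref,
                            sd_draw = sd_fun, n_boot = n_boot, conf = conf,
                            seed = seed)
  new_prevalence_estimate("probit_I", cutoff_mm,
                          probit_point(mean(x), sd_ref, cutoff_mm),
                          ci$ci_low, ci$ci_high, length(x),
                          mean_muac_mm = mean(x), sd_used_mm = sd_ref,
                          se_z = ci$se_z, conf = conf)
}

#' PROBIT prevalence estimate with the sample SD
#'
#' The point estimate is `pnorm((cutoff - sample mean) / sample SD)`; the CI
#' comes from [probit_bootstrap_ci()] with both mean and SD recomputed on
#' each (cluster) bootstrap resample.
#'
#' @inheritParams probit_I_estimate
#' @return A `prevalence_estimate`.
#' @examples
#' s <- tibble::tibble(muac_mm = rnorm(100, 135, 12), design = "simple_random")
#' probit_II_estimate(s, 125, n_boot = 200, seed = 1)
#' @export
probit_II_estimate <- function(data, cutoff_mm, n_boot = 2000, seed = NULL,
                               conf = 0.95) {
  check_survey(data)
  x <- data$muac_mm[!is.na(data$muac_mm)]
  if (length(x) < 2) abort("sample-SD PROBIT needs at least 2 records")
  s_hat <- sd(x)
  if (s_hat <= 0) abort("degenerate sample: MUAC SD must be strictly positive")
  ci <- probit_bootstrap_ci(data, cutoff_mm, point_sd = s_hat,
                            sd_draw = NULL, n_boot = n_boot, conf = conf,
                            seed = seed)
  new_prevalence_estimate("probit_II", cutoff_mm,
                          probit_point(mean(x), s_hat, cutoff_mm),
                          ci$ci_low, ci$ci_high, length(x),
                          mean_muac_mm = mean(x), sd_used_mm = s_hat,
                          se_z = ci$se_z, conf = conf)
}
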