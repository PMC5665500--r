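# quick child-record tibble: muac values, optional cluster labels
make_survey <- function(muac, cluster = NULL, survey_id = "s1",
                        region = "east_africa", design = NULL, ...) {
  design <- design %||% if (is.null(cluster)) "simple_random" else "clustered"
  tibble::tibble(
    survey_id = survey_id,
    cluster_id = if (is.null(cluster)) NA_character_ else as.character(cluster),
    muac_mm = muac,
    design = design,
    region = region,
    ...)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_survey_csv <- function(df, path = tempfile(fileext = ".csv")) {
  readr::write_csv(df, path)
  path
}

# independent oracle for the normal CDF: numerical integration of the
# standard normal density (never pnorm)
phi_oracle <- function(z) {
  vapply(z, function(zz) {
    if (zz < 0) {
      0.5 - stats::integrate(function(t) exp(-t^2 / 2) / sqrt(2 * pi),
                             zz, 0, rel.tol = 1e-10)$value
    } else {
      0.5 + stats::integrate(function(t) exp(-t^2 / 2) / sqrt(2 * pi),
                             0, zz, rel.tol = 1e-10)$value
    }
  }, numeric(1))
}

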