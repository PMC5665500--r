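#' Read child-level MUAC survey data from CSV
#'
#' Reads a CSV of one row per measured child and returns a survey tibble, the
#' tabular currency of the package. Expected columns (remappable through
#' `col_map`): `survey_id`, `cluster_id`, `muac_mm`, and optionally `region`,
#' `livelihood`, `residence`, `design`, `date_period`. MUAC is in millimetres.
#'
#' Survey design is taken from the `design` column when present; otherwise it
#' is inferred: rows with a non-missing `cluster_id` form a clustered survey,
#' a file without usable cluster ids is treated as simple random.
#'
#' @param path Path to a CSV file.
#' @param col_map Optional named character vector mapping package column
#'   names to file column names, e.g. `c(muac_mm = "muac")`.
#' @return A tibble with one row per child and at least the columns
#'   `survey_id`, `cluster_id`, `muac_mm`, `design`.
#' @examples
#' path <- system.file("extdata", "demo_surveys.csv", package = "muacprobit")
#' head(read_survey_csv(path))
#' @export
read_survey_csv <- function(path, col_map = NULL) {
  if (!file.exists(path)) {
    abort(paste0("survey file not found: ", path))
  }
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  if (!is.null(col_map)) {
    missing_src <- setdiff(unname(col_map), names(raw))
    if (length(missing_src) > 0) {
      abort(paste0("column(s) mapped but absent from file: ",
                   paste(missing_src, collapse = ", ")))
    }
    for (i in seq_along(col_map)) {
      names(raw)[names(raw) == col_map[[i]]] <- names(col_map)[i]
    }
  }
  required <- c("survey_id", "muac_mm")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0("missing required column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }

  muac_chr <- raw$muac_mm
  muac_num <- suppressWarnings(as.numeric(muac_chr))
  bad <- which(!is.na(muac_chr) & trimws(muac_chr) != "" & is.na(muac_num))
  if (length(bad) > 0) {
    abort(paste0("non-numeric MUAC value '", muac_chr[bad[1]],
                 "' in data row ", bad[1],
                 if (length(bad) > 1) paste0(" (and ", length(bad) - 1,
                                             " further row(s))") else ""))
  }
  out <- as_tibble(raw)
  out$muac_mm <- muac_num
  if (!"cluster_id" %in% names(out)) out$cluster_id <- NA_character_
  out$cluster_id[!is.na(out$cluster_id) & trimws(out$cluster_id) == ""] <-
    NA_character_
  if (!"design" %in% names(out) || all(is.na(out$design))) {
    out$design <- ifelse(is.na(out$cluster_id), "simple_random", "clustered")
    # a survey is clustered as a whole, not row by row
    out <- out %>%
      group_by(.data$survey_id) %>%
      mutate(design = if (any(.data$design == "clustered"))
        "clustered" else "simple_random") %>%
      ungroup()
  }
  out
}

# internal: validate the columns a computation needs; returns invisibly
check_survey <- function(data, require = "muac_mm", arg = "data") {
  if (!is.data.frame(data)) {
    abort(paste0("`", arg, "` must be a data frame of child records"))
  }
  missing_cols <- setdiff(require, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("`", arg, "` lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  invisible(data)
}

# internal: survey design of a sample, from the design column or cluster ids
survey_design <- function(data) {
  if ("design" %in% names(data) && nrow(data) > 0 && !is.na(data$design[1])) {
    d <- as.character(data$design[1])
    if (!d %in% .DESIGNS) abort(paste0("unknown survey design: ", d))
    return(d)
  }
  if ("cluster_id" %in% names(data) && any(!is.na(data$cluster_id))) {
    "clustered"
  } else {
    "simple_random"
  }
}

#' Remove implausible MUAC values
#'
#' Drops records whose MUAC lies outside a fixed plausibility range, the
#' field-standard fixed-range flagging used before any prevalence work.
#' Records with missing MUAC are always dropped and counted. The cleaning
#' report is attached as an attribute and retrievable with
#' [cleaning_report()].
#'
#' @param data A survey tibble with a `muac_mm` column.
#' @param bounds Length-2 numeric, inclusive plausibility bounds in mm.
#'   The default 80--220 mm spans the physiological range for children
#'   under five.
#' @return The cleaned tibble (rows with `bounds[1] <= muac_mm <= bounds[2]`),
#'   with a `cleaning_report` attribute.
#' @examples
#' s <- tibble::tibble(survey_id = "s1", muac_mm = c(90, 125, 300))
#' cleaned <- clean_muac(s)
#' cleaning_report(cleaned)
#' @export
clean_muac <- function(data, bounds = c(80, 220)) {
  check_survey(data)
  if (length(bounds) != 2 || !is.numeric(bounds) || bounds[1] >= bounds[2]) {
    abort("`bounds` must be numeric of length 2 with bounds[1] < bounds[2]")
  }
  keep <- !is.na(data$muac_mm) &
    data$muac_mm >= bounds[1] & data$muac_mm <= bounds[2]
  out <- data[keep, , drop = FALSE]
  if (nrow(out) == 0) {
    abort("cleaning excluded every record; check `bounds` and the MUAC unit (mm)")
  }
  report <- list(n_input = nrow(data),
                 n_excluded = sum(!keep),
                 bounds_used = as.numeric(bounds))
  attr(out, "cleaning_report") <- report
  out
}

#' @rdname clean_muac
#' @param x A tibble returned by [clean_muac()].
#' @export
cleaning_report <- function(x) {
  attr(x, "cleaning_report")
}

#' Population ("true") prevalence below a MUAC cutoff
#'
#' The proportion of children with MUAC strictly below the cutoff. Applied to
#' a source survey treated as a population it gives the truth against which
#' small-sample estimates are judged. A child exactly at the cutoff is not a
#' case (case definitions are `MUAC < 115` mm for SAM, `< 125` mm for GAM).
#'
#' @param data A survey tibble with a `muac_mm` column.
#' @param cutoff_mm Case-defining cutoff in mm (115 for SAM, 125 for GAM).
#' @return A proportion in `[0, 1]`.
#' @examples
#' s <- tibble::tibble(muac_mm = c(110, 120, 130, 140))
#' true_prevalence(s, 125)
#' @export
true_prevalence <- function(data, cutoff_mm) {
  check_survey(data)
  x <- data$muac_mm
  x <- x[!is.na(x)]
  if (length(x) == 0) abort("empty dataset: no non-missing MUAC values")
  mean(x < cutoff_mm)
}
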