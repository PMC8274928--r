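# Run configuration, the top-level pipeline entry point, and report
# writing (group-mean tables plus machine-readable CSVs).

#' Validated run configuration for the full pipeline
#'
#' @param inflation_csv,histology_csv Optional input CSV paths; when `NULL`
#'   the corresponding stage is skipped (or, for [run_pipeline()] with
#'   `simulate = TRUE`, data are generated).
#' @param output_dir Directory for report files; created if absent.
#' @param alpha Significance threshold in (0, 1).
#' @param pressure_range Pressure range for curve maxima, mmHg.
#' @param min_points Minimum distinct pressures per fit; at least 4.
#' @param seed Integer seed for any simulated stage.
#' @param curve_kinds Curve kinds for the age comparison.
#' @param plots Write curve-family figures?
#' @return A `run_config` list.
#' @export
run_config <- function(inflation_csv = NULL, histology_csv = NULL,
                       output_dir = tempfile("vasofit_run_"),
                       alpha = 0.05, pressure_range = c(15, 300),
                       min_points = 5L, seed = 1L,
                       curve_kinds = c("area", "compliance",
                                       "distensibility"),
                       plots = FALSE) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1) {
    stop("`alpha` must lie in (0, 1)", call. = FALSE)
  }
  check_pressure_range(pressure_range)
  if (!is.numeric(min_points) || min_points < 4) {
    stop("`min_points` must be at least 4", call. = FALSE)
  }
  curve_kinds <- match.arg(curve_kinds, several.ok = TRUE)
  structure(list(inflation_csv = inflation_csv,
                 histology_csv = histology_csv,
                 output_dir = output_dir, alpha = alpha,
                 pressure_range = pressure_range,
                 min_points = as.integer(min_points),
                 seed = as.integer(seed), curve_kinds = curve_kinds,
                 plots = isTRUE(plots)),
            class = "run_config")
}

fmt_mean_sd <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) == 0L) return(NA_character_)
  sprintf("%.3g ± %.2g", mean(x), stats::sd(x))
}

# location x age table of "mean +/- sd" strings for the given columns
group_mean_table <- function(tbl, value_cols) {
  tbl |>
    dplyr::group_by(.data$location, .data$age_group) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(value_cols), fmt_mean_sd),
                     .groups = "drop") |>
    dplyr::arrange(.data$location, dplyr::desc(.data$age_group))
}

#' Write a combined analysis report
#'
#' Produces a human-readable `summary.txt` (location x age-group mean +/-
#' SD tables for the inflation summary metrics and the histomorphometry
#' outcomes, plus the curve-comparison and ANOVA results) and
#' machine-readable CSVs next to it. Stages whose inputs are absent are
#' marked absent in the summary rather than omitted.
#'
#' @param output_dir Output directory, created if needed.
#' @param inflation_metrics Per-sample table from [process_dataset()], or
#'   `NULL`.
#' @param curve_tests Table from [compare_age_groups()], or `NULL`.
#' @param metric_anova `vasofit_anova` from [anova_summary_metrics()], or
#'   `NULL`.
#' @param histo_metrics Per-horse table from [aggregate_histology()], or
#'   `NULL`.
#' @param histology_anova `vasofit_anova` from [histo_anova()], or `NULL`.
#' @return Character vector of the files written, invisibly.
#' @export
report <- function(output_dir, inflation_metrics = NULL, curve_tests = NULL,
                   metric_anova = NULL, histo_metrics = NULL,
                   histology_anova = NULL) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  lines <- c("vasofit analysis report", strrep("=", 40), "")
  put <- function(x) lines <<- c(lines, x)
  save_csv <- function(tbl, name) {
    f <- file.path(output_dir, name)
    readr::write_csv(tbl, f, progress = FALSE)
    files <<- c(files, f)
  }
  if (!is.null(inflation_metrics)) {
    save_csv(inflation_metrics, "inflation_metrics.csv")
    gm <- group_mean_table(inflation_metrics,
                           c("max_area_mm2", "max_compliance_mm2_mmHg",
                             "max_distensibility_per_mmHg"))
    save_csv(gm, "inflation_group_means.csv")
    put(c("Inflation-extension summary metrics (mean ± SD)",
          utils::capture.output(print(as.data.frame(gm), row.names = FALSE)),
          ""))
    n_bad <- sum(inflation_metrics$fit_status != "converged")
    if (n_bad > 0L) {
      put(c(sprintf("Samples not fitted cleanly: %d (see fit_status column)",
                    n_bad), ""))
    }
  } else {
    put(c("Inflation-extension section: absent (no inflation input)", ""))
  }
  if (!is.null(curve_tests)) {
    save_csv(curve_tests, "curve_comparisons.csv")
    put(c("Age-group curve comparisons (nested F-tests)",
          utils::capture.output(print(as.data.frame(
            curve_tests[, c("location", "curve_kind", "f_statistic",
                            "df_num", "df_den", "p_value", "degenerate")]),
            row.names = FALSE)), ""))
  }
  if (!is.null(metric_anova)) {
    save_csv(metric_anova$effects, "metric_anova_effects.csv")
    put(c("Summary-metric ANOVA",
          utils::capture.output(print(as.data.frame(metric_anova$effects),
                                      row.names = FALSE)), ""))
  }
  if (!is.null(histo_metrics)) {
    save_csv(histo_metrics, "histology_metrics.csv")
    gm <- group_mean_table(histo_metrics,
                           c("imt_um", "elastin_pct", "sma_pct", "col1_pct",
                             "col3_pct"))
    save_csv(gm, "histology_group_means.csv")
    put(c("Histomorphometry (mean ± SD)",
          utils::capture.output(print(as.data.frame(gm), row.names = FALSE)),
          ""))
  } else {
    put(c("Histology section: absent (no histology input)", ""))
  }
  if (!is.null(histology_anova)) {
    save_csv(histology_anova$effects, "histology_anova_effects.csv")
    put(c("Histomorphometry ANOVA (horse as random intercept)",
          utils::capture.output(print(as.data.frame(histology_anova$effects),
                                      row.names = FALSE)), ""))
  }
  f <- file.path(output_dir, "summary.txt")
  writeLines(lines, f, useBytes = TRUE)
  files <- c(files, f)
  invisible(files)
}

#' Run the full analysis pipeline
#'
#' Reads (or simulates) inflation and histology data, fits every sample,
#' compares age-group curves per location, runs the summary-metric and
#' histomorphometry ANOVAs, and writes the report.
#'
#' @param config A [run_config()].
#' @param simulate Generate synthetic inputs (with `config$seed`) for any
#'   stage whose input CSV is `NULL`.
#' @return List with `inflation_metrics`, `curve_tests`, `metric_anova`,
#'   `histo_metrics`, `histology_anova`, `files` (report files written).
#' @export
run_pipeline <- function(config = run_config(), simulate = is.null(config$inflation_csv)) {
  stopifnot(inherits(config, "run_config"))
  records <- histo_records <- NULL
  if (!is.null(config$inflation_csv)) {
    records <- read_inflation_csv(config$inflation_csv)
  } else if (simulate) {
    records <- gen_inflation_dataset(seed = config$seed)$records
  }
  if (!is.null(config$histology_csv)) {
    histo_records <- read_histology_csv(config$histology_csv)
  } else if (simulate) {
    histo_records <- gen_histology_dataset(seed = config$seed)
  }
  inflation_metrics <- curve_tests <- metric_anova <- NULL
  histo_metrics <- histology_anova <- NULL
  if (!is.null(records)) {
    inflation_metrics <- process_dataset(records, config$pressure_range,
                                         config$min_points)
    curve_tests <- compare_age_groups(records, config$curve_kinds)
    metric_anova <- anova_summary_metrics(inflation_metrics,
                                          alpha = config$alpha)
    if (config$plots) {
      dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
      for (kind in config$curve_kinds) {
        plot_curve_families(records, kind,
                            pressure_range = config$pressure_range,
                            path = file.path(config$output_dir,
                                             paste0("curves_", kind, ".png")))
      }
    }
  }
  if (!is.null(histo_records)) {
    histo_metrics <- aggregate_histology(histo_records)
    histology_anova <- histo_anova(histo_metrics, alpha = config$alpha)
  }
  files <- report(config$output_dir, inflation_metrics, curve_tests,
                  metric_anova, histo_metrics, histology_anova)
  list(inflation_metrics = inflation_metrics, curve_tests = curve_tests,
       metric_anova = metric_anova, histo_metrics = histo_metrics,
       histology_anova = histology_anova, files = files)
}
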