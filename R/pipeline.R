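# From raw replicate diameter measurements to pressure-area series, fitted
# curves and summary metrics for a whole dataset.

#' The standard inflation pressure grid
#'
#' The ten quasi-static pressure steps at which diameters are recorded
#' during the inflation-extension protocol, mmHg.
#'
#' @return Numeric vector of length 10.
#' @export
protocol_pressure_grid <- function() {
  c(15, 30, 45, 60, 80, 100, 125, 200, 250, 300)
}

#' Canonical vessel locations
#'
#' The seven sampling locations, as an open enumeration (other names are
#' accepted downstream but flagged). The four mechanically tested locations
#' are marked in the `testable` attribute.
#'
#' @return Character vector of location names; attribute `testable` gives
#'   the subset that undergoes inflation-extension testing.
#' @export
vessel_locations <- function() {
  locs <- c("proximal_aorta", "distal_aorta", "common_carotid",
            "cranial_common_carotid", "external_iliac", "femoral", "median")
  attr(locs, "testable") <- c("proximal_aorta", "distal_aorta",
                              "common_carotid", "external_iliac")
  locs
}

#' Mean of replicate diameter measurements
#'
#' Replicates are averaged at the diameter level (the order in which the
#' measurement protocol states it), before any conversion to area.
#'
#' @param diameters Numeric vector of replicate inner diameters, mm; all
#'   must be positive.
#' @return Arithmetic mean diameter, mm.
#' @examples
#' mean_diameter(c(9.9, 10.0, 10.1))
#' @export
mean_diameter <- function(diameters) {
  if (!is.numeric(diameters) || length(diameters) < 1L) {
    stop("need at least one replicate diameter", call. = FALSE)
  }
  if (anyNA(diameters) || any(diameters <= 0)) {
    stop("replicate diameters must all be positive (mm)", call. = FALSE)
  }
  mean(diameters)
}

#' Convert an inner diameter to a lumen area
#'
#' Circular-lumen assumption: `area = pi * (d/2)^2`.
#'
#' @param diameter Inner diameter(s), mm; positive.
#' @return Lumen area(s), mm^2.
#' @examples
#' diameter_to_area(10) # pi * 25
#' @export
diameter_to_area <- function(diameter) {
  if (!is.numeric(diameter) || anyNA(diameter) || any(diameter <= 0)) {
    stop("`diameter` must be positive (mm)", call. = FALSE)
  }
  pi * (diameter / 2)^2
}

#' Construct a pressure-area series
#'
#' Low-level constructor; most users will use [build_series()] on raw
#' records instead.
#'
#' @param sample_id Sample identifier.
#' @param pressures Strictly increasing pressures, mmHg.
#' @param areas Positive lumen areas, mm^2, one per pressure.
#' @param truncated_at Optional rupture pressure, mmHg, when the series ends
#'   before the top of the protocol grid because the vessel failed.
#' @return Object of class `pa_series`.
#' @export
new_pa_series <- function(sample_id, pressures, areas, truncated_at = NA_real_) {
  stopifnot(is.numeric(pressures), is.numeric(areas))
  if (length(pressures) != length(areas) || length(pressures) < 1L) {
    stop("`pressures` and `areas` must have equal positive length", call. = FALSE)
  }
  if (is.unsorted(pressures, strictly = TRUE)) {
    stop("`pressures` must be strictly increasing", call. = FALSE)
  }
  if (anyNA(areas) || any(areas <= 0)) {
    stop("`areas` must be positive", call. = FALSE)
  }
  structure(list(sample_id = sample_id, pressures = pressures, areas = areas,
                 truncated_at = truncated_at),
            class = "pa_series")
}

#' @export
print.pa_series <- function(x, ...) {
  cat(sprintf("Pressure-area series '%s': %d points, %g-%g mmHg%s\n",
              x$sample_id, length(x$pressures), min(x$pressures),
              max(x$pressures),
              if (is.finite(x$truncated_at)) {
                sprintf(" (ruptured at %g mmHg)", x$truncated_at)
              } else ""))
  invisible(x)
}

#' Build a pressure-area series from one sample's raw records
#'
#' Averages the replicate diameters at each pressure, converts the mean
#' diameter to a circular lumen area, and orders by pressure. If the
#' records carry a rupture pressure (`rupture_pressure_mmHg`) and the grid
#' stops before 300 mmHg, `truncated_at` is set; pressure points at or
#' above the rupture pressure are excluded from the series.
#'
#' @param records Data frame for a single sample with columns `sample_id`,
#'   `pressure_mmHg`, `diameter_mm` (one row per replicate) and optionally
#'   `rupture_pressure_mmHg`.
#' @return A `pa_series`.
#' @export
build_series <- function(records) {
  stopifnot(is.data.frame(records))
  need <- c("sample_id", "pressure_mmHg", "diameter_mm")
  missing_cols <- setdiff(need, names(records))
  if (length(missing_cols) > 0L) {
    stop("records are missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  ids <- unique(records$sample_id)
  if (length(ids) != 1L) {
    stop("records span multiple sample_ids: ", paste(ids, collapse = ", "),
         call. = FALSE)
  }
  rupture <- NA_real_
  if ("rupture_pressure_mmHg" %in% names(records)) {
    rp <- unique(records$rupture_pressure_mmHg[is.finite(records$rupture_pressure_mmHg)])
    if (length(rp) > 1L) {
      stop("inconsistent rupture pressure within sample ", ids, call. = FALSE)
    }
    if (length(rp) == 1L) rupture <- rp
  }
  by_p <- split(records$diameter_mm, records$pressure_mmHg)
  n_rep <- vapply(by_p, length, integer(1L))
  first_rep <- n_rep[[1L]]
  if (any(n_rep != first_rep)) {
    stop("unequal replicate counts across pressures for sample ", ids,
         " (duplicate or missing pressure rows?)", call. = FALSE)
  }
  pressures <- as.numeric(names(by_p))
  o <- order(pressures)
  pressures <- pressures[o]
  areas <- vapply(by_p[o], function(d) diameter_to_area(mean_diameter(d)),
                  numeric(1L))
  if (is.finite(rupture)) {
    keep <- pressures < rupture
    pressures <- pressures[keep]
    areas <- areas[keep]
  }
  new_pa_series(ids, pressures, unname(areas), truncated_at = rupture)
}

# Split a long-format record table into one pa_series per sample, carrying
# sample metadata alongside.
split_series <- function(records) {
  stopifnot(is.data.frame(records))
  if (nrow(records) == 0L) stop("empty record table", call. = FALSE)
  keys <- unique(records[, intersect(
    c("sample_id", "horse_id", "age_group", "location"), names(records)),
    drop = FALSE])
  if (anyDuplicated(keys$sample_id)) {
    stop("sample_id maps to more than one horse/age/location", call. = FALSE)
  }
  series <- lapply(split(records, records$sample_id), build_series)
  list(meta = tibble::as_tibble(keys[order(keys$sample_id), , drop = FALSE]),
       series = series[sort(names(series))])
}

#' Process a whole inflation dataset
#'
#' Runs the full per-sample pipeline over a long-format record table:
#' replicate averaging, area conversion, arctangent fitting and summary
#' metrics. Samples that cannot be fitted (truncated below the minimum
#' number of distinct pressures, degenerate signal, optimiser failure) are
#' reported with their `fit_status`, never dropped silently.
#'
#' @param records Long-format data frame, one row per sample x pressure x
#'   replicate, with columns `sample_id`, `horse_id`, `age_group`,
#'   `location`, `pressure_mmHg`, `replicate_index`, `diameter_mm` and
#'   optionally `rupture_pressure_mmHg` (see [read_inflation_csv()]).
#' @param pressure_range Range over which curve maxima are sought, mmHg.
#' @param min_points Minimum distinct pressures for a fit (default 5).
#' @return Tibble with one row per sample: identifiers, `n_points`,
#'   `truncated_at`, `fit_status`, `converged`, fitted `Am_mm2`, `P0_mmHg`,
#'   `P1_mmHg`, `rss`, `r_squared`, `max_area_mm2`, `max_measured_area_mm2`,
#'   `max_compliance_mm2_mmHg`, `p_at_max_compliance_mmHg`,
#'   `max_distensibility_per_mmHg`, `p_at_max_distensibility_mmHg`.
#'   `max_area_mm2` is the fitted asymptote `Am`; the largest measured area
#'   is reported separately so both readings of "maximal area" are
#'   available.
#' @examples
#' sim <- gen_inflation_dataset(n_young = 2, n_old = 2, seed = 1)
#' head(process_dataset(sim$records))
#' @export
process_dataset <- function(records, pressure_range = c(15, 300),
                            min_points = 5L) {
  check_pressure_range(pressure_range)
  parts <- split_series(records)
  rows <- purrr::map2(parts$series, names(parts$series), function(s, id) {
    fit <- tryCatch(
      fit_arctangent(s, min_points = min_points),
      vasofit_insufficient_data = function(e) {
        list(params = NULL, rss = NA_real_, r_squared = NA_real_,
             n_points = length(s$pressures), converged = FALSE,
             status = "insufficient_data")
      })
    base <- tibble::tibble(
      sample_id = id,
      n_points = length(s$pressures),
      truncated_at = s$truncated_at,
      fit_status = fit$status,
      converged = fit$converged,
      max_measured_area_mm2 = max(s$areas)
    )
    if (is.null(fit$params)) {
      return(dplyr::bind_cols(base, tibble::tibble(
        Am_mm2 = NA_real_, P0_mmHg = NA_real_, P1_mmHg = NA_real_,
        rss = NA_real_, r_squared = NA_real_,
        max_area_mm2 = NA_real_, max_compliance_mm2_mmHg = NA_real_,
        p_at_max_compliance_mmHg = NA_real_,
        max_distensibility_per_mmHg = NA_real_,
        p_at_max_distensibility_mmHg = NA_real_
      )))
    }
    sm <- summary_metrics(fit$params, pressure_range)
    dplyr::bind_cols(base, tibble::tibble(
      Am_mm2 = fit$params$Am, P0_mmHg = fit$params$P0, P1_mmHg = fit$params$P1,
      rss = fit$rss, r_squared = fit$r_squared
    ), sm)
  })
  out <- dplyr::bind_rows(rows)
  dplyr::relocate(dplyr::left_join(parts$meta, out, by = "sample_id"),
                  "sample_id")
}

#' Finite-difference empirical compliance and distensibility
#'
#' Converts a measured pressure-area series into empirical compliance
#' points by forward differences, `(A[i+1] - A[i]) / (P[i+1] - P[i])`
#' placed at the interval midpoint, and empirical distensibility as that
#' value divided by the midpoint-interpolated area. These data-level points
#' carry residual scatter and are what the curve-comparison F-tests for
#' compliance and distensibility are fitted to.
#'
#' @param series A `pa_series` (or data frame with `pressure_mmHg`,
#'   `area_mm2`) of length at least 2.
#' @return Tibble with columns `pressure_mmHg` (midpoints),
#'   `compliance_mm2_mmHg`, `area_mm2` (midpoint-interpolated),
#'   `distensibility_per_mmHg`.
#' @examples
#' p <- arctan_params(1000, 110, 40)
#' grid <- protocol_pressure_grid()
#' empirical_compliance(new_pa_series("s", grid, area_at(p, grid)))
#' @export
empirical_compliance <- function(series) {
  xy <- series_points(series)
  n <- length(xy$pressure)
  if (n < 2L) stop("need at least 2 points for empirical compliance", call. = FALSE)
  dP <- diff(xy$pressure)
  dA <- diff(xy$area)
  mid_p <- xy$pressure[-n] + dP / 2
  mid_a <- (xy$area[-n] + xy$area[-1L]) / 2
  comp <- dA / dP
  tibble::tibble(
    pressure_mmHg = mid_p,
    compliance_mm2_mmHg = comp,
    area_mm2 = mid_a,
    distensibility_per_mmHg = comp / mid_a
  )
}
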