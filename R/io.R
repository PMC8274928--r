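# CSV interchange for inflation and histology tables, with row-level
# validation. The canonical formats are long: one row per sample x
# pressure x replicate (inflation) and one row per horse x location x
# layer x stain x frame (histology).

inflation_cols <- function() {
  c("sample_id", "horse_id", "age_group", "location", "pressure_mmHg",
    "replicate_index", "diameter_mm")
}

histology_cols <- function() {
  c("horse_id", "age_group", "location", "layer", "stain", "frame_index",
    "area_pct", "thickness_um")
}

stop_rows <- function(bad, what) {
  stop(what, " at row(s) ", paste(utils::head(bad, 10L), collapse = ", "),
       if (length(bad) > 10L) sprintf(" (and %d more)", length(bad) - 10L),
       call. = FALSE)
}

check_required_cols <- function(tbl, need, path) {
  missing_cols <- setdiff(need, names(tbl))
  if (length(missing_cols) > 0L) {
    hint <- if (any(grepl("^diameter_[0-9]+$|^d[123]$", names(tbl)))) {
      " (the table looks wide-format; supply long format with one row per replicate and a replicate_index column)"
    } else ""
    stop("'", path, "' is missing column(s): ",
         paste(missing_cols, collapse = ", "), hint, call. = FALSE)
  }
}

#' Read and validate an inflation-extension CSV
#'
#' Long format, UTF-8, header required; columns `sample_id`, `horse_id`,
#' `age_group` (`young`/`old`), `location`, `pressure_mmHg`,
#' `replicate_index`, `diameter_mm`, optional `rupture_pressure_mmHg`.
#' Validation failures name the offending rows. A pressure grid other than
#' the standard protocol grid is accepted but flagged with a warning, as is
#' a replicate count other than 3.
#'
#' @param path CSV file path.
#' @return Validated tibble of records.
#' @export
read_inflation_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  tbl <- readr::read_csv(path, show_col_types = FALSE,
                         progress = FALSE)
  if (nrow(tbl) == 0L) stop("'", path, "' contains no data rows", call. = FALSE)
  check_required_cols(tbl, inflation_cols(), path)
  if ("rupture_pressure_mmHg" %in% names(tbl)) {
    # an all-NA column parses as logical; the schema says numeric
    tbl$rupture_pressure_mmHg <- as.numeric(tbl$rupture_pressure_mmHg)
  }
  for (col in c("pressure_mmHg", "replicate_index", "diameter_mm")) {
    if (!is.numeric(tbl[[col]])) {
      stop("column '", col, "' in '", path, "' is not numeric", call. = FALSE)
    }
  }
  bad <- which(!is.finite(tbl$diameter_mm) | tbl$diameter_mm <= 0)
  if (length(bad) > 0L) stop_rows(bad, "non-positive or missing diameter_mm")
  bad <- which(!tbl$age_group %in% c("young", "old"))
  if (length(bad) > 0L) stop_rows(bad, "age_group must be 'young' or 'old'")
  bad <- which(!is.finite(tbl$pressure_mmHg) | tbl$pressure_mmHg <= 0)
  if (length(bad) > 0L) stop_rows(bad, "non-positive or missing pressure_mmHg")
  off_grid <- setdiff(unique(tbl$pressure_mmHg), protocol_pressure_grid())
  if (length(off_grid) > 0L) {
    warning("pressure grid differs from the standard protocol grid (extra: ",
            paste(utils::head(off_grid, 5L), collapse = ", "), ")",
            call. = FALSE)
  }
  n_rep <- tbl |>
    dplyr::count(.data$sample_id, .data$pressure_mmHg)
  if (any(n_rep$n != 3L)) {
    warning("replicate count differs from the protocol's 3 for some sample/pressure combinations",
            call. = FALSE)
  }
  unknown_loc <- setdiff(unique(tbl$location), vessel_locations())
  if (length(unknown_loc) > 0L) {
    warning("non-canonical location name(s): ",
            paste(unknown_loc, collapse = ", "), call. = FALSE)
  }
  tbl
}

#' Write an inflation record table to CSV
#'
#' @param records Record tibble (see [read_inflation_csv()] for the schema).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_inflation_csv <- function(records, path) {
  check_required_cols(records, inflation_cols(), "records")
  readr::write_csv(records, path, progress = FALSE)
  invisible(path)
}

#' Read and validate a histology CSV
#'
#' Long format; columns `horse_id`, `age_group`, `location`, `layer`,
#' `stain`, `frame_index`, `area_pct`, `thickness_um`. Area percentages
#' outside \[0, 100\] are rejected at parse time (not clipped); thickness
#' may be `NA` (proximal aorta, where wall thickness is not assessed) but
#' must otherwise be positive.
#'
#' @param path CSV file path.
#' @return Validated tibble of records.
#' @export
read_histology_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  tbl <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (nrow(tbl) == 0L) stop("'", path, "' contains no data rows", call. = FALSE)
  check_required_cols(tbl, histology_cols(), path)
  bad <- which(!is.finite(tbl$area_pct) | tbl$area_pct < 0 | tbl$area_pct > 100)
  if (length(bad) > 0L) stop_rows(bad, "area_pct outside [0, 100]")
  bad <- which(is.finite(tbl$thickness_um) & tbl$thickness_um <= 0)
  if (length(bad) > 0L) stop_rows(bad, "non-positive thickness_um")
  bad <- which(!tbl$age_group %in% c("young", "old"))
  if (length(bad) > 0L) stop_rows(bad, "age_group must be 'young' or 'old'")
  bad <- which(!tbl$stain %in% histo_stains())
  if (length(bad) > 0L) {
    stop_rows(bad, paste0("stain must be one of ",
                          paste(histo_stains(), collapse = ", ")))
  }
  tbl
}

#' Write a histology record table to CSV
#'
#' @param records Record tibble (see [read_histology_csv()] for the schema).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_histology_csv <- function(records, path) {
  check_required_cols(records, histology_cols(), "records")
  readr::write_csv(records, path, progress = FALSE)
  invisible(path)
}
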