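# Layered histomorphometry: frame averaging, thickness-weighted overall
# stain area percentages, and mixed-model ANOVA with horse as random
# intercept.

#' Mean of repeated frame or thickness measurements
#'
#' Five measurements (image frames for stain area %, random locations for
#' wall thickness) are taken per slide and averaged before any further
#' aggregation.
#'
#' @param values Numeric measurements; at least one.
#' @param domain Closed admissible interval; defaults to `c(0, 100)` for
#'   stain area percentages. Use `c(0, Inf)` for thicknesses.
#' @return Arithmetic mean.
#' @examples
#' mean_of_frames(c(10, 12, 14, 16, 18))
#' @export
mean_of_frames <- function(values, domain = c(0, 100)) {
  if (!is.numeric(values) || length(values) < 1L || anyNA(values)) {
    stop("need at least one numeric measurement", call. = FALSE)
  }
  if (any(values < domain[1L] | values > domain[2L])) {
    stop("measurement outside [", domain[1L], ", ", domain[2L], "]",
         call. = FALSE)
  }
  mean(values)
}

#' Thickness-weighted overall stain area percentage
#'
#' When the tunica media splits into two layers (an inner smooth-muscle-rich
#' layer and an outer elastin-fibre-rich layer), per-layer stain area
#' percentages are combined into an overall value by weighting each layer
#' with its share of the total thickness:
#' \deqn{overall = pct_1 \frac{t_1}{t_1+t_2} + pct_2 \frac{t_2}{t_1+t_2}}
#' A zero second-layer thickness (single-layer wall, e.g. the proximal
#' aorta) degenerates to the first layer's value; `pct2` may then be `NA`.
#'
#' @param pct1,pct2 Mean stain area % of layer 1 and 2, in \[0, 100\].
#' @param t1,t2 Mean layer thicknesses, um, non-negative with `t1 + t2 > 0`.
#' @return Overall area %, a convex combination of the layer values.
#' @examples
#' overall_area_percent(40, 600, 10, 400) # 28
#' @export
overall_area_percent <- function(pct1, t1, pct2, t2) {
  stopifnot(is.numeric(t1), is.numeric(t2))
  if (anyNA(c(t1, t2)) || t1 < 0 || t2 < 0 || t1 + t2 <= 0) {
    stop("layer thicknesses must be non-negative with positive total",
         call. = FALSE)
  }
  check_pct <- function(p, nm) {
    if (!is.numeric(p) || is.na(p) || p < 0 || p > 100) {
      stop("`", nm, "` must be an area % in [0, 100]", call. = FALSE)
    }
  }
  check_pct(pct1, "pct1")
  if (t2 == 0) return(pct1)
  check_pct(pct2, "pct2")
  (pct1 * t1 + pct2 * t2) / (t1 + t2)
}

histo_stains <- function() c("elastin", "sma", "col1", "col3")

#' Aggregate raw histology records to per-horse overall wall metrics
#'
#' For each horse x location: frame values are averaged per layer and
#' stain ([mean_of_frames()]), thickness measurements are averaged per
#' layer, and two-layer walls are combined with the thickness-weighting
#' formula ([overall_area_percent()]). Aggregation follows the measurement
#' protocol's order: means first, weighting second. Intima-media thickness
#' is the sum of the layer mean thicknesses; it is `NA` where thickness was
#' not assessed (proximal aorta).
#'
#' @param records Long-format data frame with columns `horse_id`,
#'   `age_group`, `location`, `layer`, `stain`, `frame_index`, `area_pct`,
#'   `thickness_um` (see [read_histology_csv()]).
#' @return Tibble, one row per horse x location: `horse_id`, `age_group`,
#'   `location`, `n_layers`, `imt_um`, `elastin_pct`, `sma_pct`,
#'   `col1_pct`, `col3_pct`.
#' @export
aggregate_histology <- function(records) {
  stopifnot(is.data.frame(records))
  need <- c("horse_id", "age_group", "location", "layer", "stain",
            "frame_index", "area_pct", "thickness_um")
  missing_cols <- setdiff(need, names(records))
  if (length(missing_cols) > 0L) {
    stop("histology records are missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(records) == 0L) stop("empty histology table", call. = FALSE)
  # validate domains once, vectorised (the per-slide arithmetic is then a
  # plain mean, identical to mean_of_frames on valid input)
  if (any(records$area_pct < 0 | records$area_pct > 100, na.rm = TRUE) ||
      anyNA(records$area_pct)) {
    stop("area_pct outside [0, 100]", call. = FALSE)
  }
  if (any(records$thickness_um <= 0, na.rm = TRUE)) {
    stop("non-positive thickness_um", call. = FALSE)
  }
  # per-layer mean thickness from the distinct (layer, frame) measurements
  th <- records |>
    dplyr::distinct(.data$horse_id, .data$age_group, .data$location,
                    .data$layer, .data$frame_index, .data$thickness_um) |>
    dplyr::group_by(.data$horse_id, .data$age_group, .data$location,
                    .data$layer) |>
    dplyr::summarise(t_mean = mean(.data$thickness_um), .groups = "drop")
  # five-frame mean per layer and stain, then thickness weighting
  pct <- records |>
    dplyr::group_by(.data$horse_id, .data$age_group, .data$location,
                    .data$layer, .data$stain) |>
    dplyr::summarise(p_mean = mean(.data$area_pct), .groups = "drop") |>
    dplyr::left_join(th, by = c("horse_id", "age_group", "location", "layer"))
  overall <- pct |>
    dplyr::group_by(.data$horse_id, .data$age_group, .data$location,
                    .data$stain) |>
    dplyr::summarise(
      n_layers = dplyr::n(),
      value = if (dplyr::n() == 1L) .data$p_mean[1L] else if
        (anyNA(.data$t_mean)) NA_real_ else
          overall_area_percent(.data$p_mean[order(.data$layer)][1L],
                               .data$t_mean[order(.data$layer)][1L],
                               .data$p_mean[order(.data$layer)][2L],
                               .data$t_mean[order(.data$layer)][2L]),
      .groups = "drop")
  imt <- th |>
    dplyr::group_by(.data$horse_id, .data$age_group, .data$location) |>
    dplyr::summarise(imt_um = if (anyNA(.data$t_mean)) NA_real_ else
      sum(.data$t_mean), .groups = "drop")
  overall |>
    tidyr::pivot_wider(names_from = "stain", values_from = "value",
                       names_glue = "{stain}_pct",
                       id_cols = c("horse_id", "age_group", "location",
                                   "n_layers")) |>
    dplyr::left_join(imt, by = c("horse_id", "age_group", "location")) |>
    dplyr::select("horse_id", "age_group", "location", "n_layers",
                  "imt_um", "elastin_pct", "sma_pct", "col1_pct",
                  "col3_pct") |>
    dplyr::arrange(.data$horse_id, .data$location)
}

#' Mixed-model ANOVA of histomorphometry outcomes
#'
#' Per outcome (intima-media thickness and overall stain area percentages),
#' fits a linear mixed model with age group and location as fixed factors
#' and horse as a random intercept (each horse contributes every location,
#' so horse is a blocking factor), using Satterthwaite F-tests
#' (\pkg{lmerTest}). Location post-hoc pairwise contrasts on estimated
#' marginal means are Bonferroni-adjusted over all `choose(k, 2)` pairs.
#' Outcomes with no variance or inestimable models are reported as
#' degenerate, not dropped silently. If the random-intercept fit fails, the
#' fallback is a fixed-effects ANOVA on the same data, flagged in the
#' per-outcome note.
#'
#' @param metrics Per horse x location table from [aggregate_histology()].
#' @param outcomes Outcome columns to analyse.
#' @param alpha Significance threshold.
#' @param include_interaction Include the age x location interaction.
#' @param posthoc Compute pairwise location contrasts (skip for speed in
#'   large simulation studies where only the omnibus F matters).
#' @return A `vasofit_anova` object (see [anova_summary_metrics()]); the
#'   `effects` table additionally records the `model` used
#'   (`"mixed"` or `"fixed_fallback"`).
#' @export
histo_anova <- function(metrics,
                        outcomes = c("imt_um", "elastin_pct", "sma_pct",
                                     "col1_pct", "col3_pct"),
                        alpha = 0.05,
                        include_interaction = FALSE,
                        posthoc = TRUE) {
  stopifnot(is.data.frame(metrics))
  missing_cols <- setdiff(c("horse_id", "age_group", "location", outcomes),
                          names(metrics))
  if (length(missing_cols) > 0L) {
    stop("metrics table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  res <- purrr::map(outcomes, function(oc) {
    mixed_anova_one(metrics, oc, alpha, include_interaction, posthoc)
  })
  names(res) <- outcomes
  structure(list(
    effects = dplyr::bind_rows(purrr::map(res, "effects")),
    posthoc = purrr::compact(purrr::map(res, "posthoc")),
    letters = purrr::compact(purrr::map(res, "letters")),
    degenerate = tibble::tibble(
      outcome = outcomes,
      degenerate = vapply(res, function(r) r$degenerate, logical(1L)),
      note = vapply(res, function(r) r$note, character(1L))
    ),
    alpha = alpha
  ), class = "vasofit_anova")
}

mixed_anova_one <- function(dat, outcome, alpha, include_interaction,
                            posthoc = TRUE) {
  y <- dat[[outcome]]
  keep <- is.finite(y)
  dat <- dat[keep, , drop = FALSE]
  res_empty <- list(effects = NULL, posthoc = NULL, letters = NULL,
                    degenerate = FALSE, note = NA_character_)
  if (nrow(dat) == 0L || length(unique(dat$age_group)) < 2L ||
      length(unique(dat$location)) < 2L) {
    res_empty$degenerate <- TRUE
    res_empty$note <- "needs >= 2 levels of age_group and location"
    return(res_empty)
  }
  n_per_age <- table(unique(dat[, c("horse_id", "age_group")])$age_group)
  if (any(n_per_age < 2L)) {
    res_empty$degenerate <- TRUE
    res_empty$note <- "needs >= 2 horses per age group"
    return(res_empty)
  }
  if (stats::var(dat[[outcome]]) == 0) {
    res_empty$degenerate <- TRUE
    res_empty$note <- "zero between-group variance"
    return(res_empty)
  }
  dat$age_group <- factor(dat$age_group)
  dat$location <- factor(dat$location)
  dat$horse_id <- factor(dat$horse_id)
  fixed <- if (include_interaction) "age_group * location" else
    "age_group + location"
  form <- stats::as.formula(paste(outcome, "~", fixed, "+ (1 | horse_id)"))
  mod <- tryCatch(
    suppressMessages(suppressWarnings(
      lmerTest::lmer(form, data = dat,
                     control = lme4::lmerControl(check.conv.singular =
                       lme4::.makeCC(action = "ignore", tol = 1e-4)))
    )),
    error = function(e) NULL)
  if (!is.null(mod)) {
    atab <- tryCatch(as.data.frame(stats::anova(mod, type = 3)),
                     error = function(e) NULL)
  } else {
    atab <- NULL
  }
  model_used <- "mixed"
  if (is.null(mod) || is.null(atab) || anyNA(atab$`F value`)) {
    # fixed-effects fallback when the random intercept is not estimable
    model_used <- "fixed_fallback"
    fb <- fixed_anova_one(dat, outcome, alpha,
                          include_interaction = include_interaction,
                          posthoc = posthoc)
    if (fb$degenerate) {
      res_empty$degenerate <- TRUE
      res_empty$note <- paste("mixed model failed;", fb$note)
      return(res_empty)
    }
    fb$effects$model <- model_used
    fb$note <- "random horse intercept not estimable; fixed-effects ANOVA used"
    return(fb)
  }
  effects <- tibble::tibble(
    outcome = outcome,
    term = rownames(atab),
    df = atab$NumDF,
    df_resid = atab$DenDF,
    f_statistic = atab$`F value`,
    p_value = atab$`Pr(>F)`,
    model = model_used
  )
  ph <- if (posthoc) location_posthoc(mod, dat, alpha) else
    list(table = NULL, letters = NULL)
  list(effects = effects, posthoc = ph$table, letters = ph$letters,
       degenerate = FALSE, note = NA_character_)
}
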