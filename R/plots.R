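# Curve-family figures: per location, individual data points of each
# sample with the fitted group curves overlaid, young vs old.

# pooled group curve: one fit to all of the group's points (default);
# mean_params: average the per-sample fitted parameters instead.
group_curve_params <- function(series_list, kind,
                               method = c("pooled", "mean_params")) {
  method <- match.arg(method)
  if (method == "pooled") {
    pts <- dplyr::bind_rows(purrr::map(series_list, curve_points, kind = kind))
    w <- 1 / pts$y^2
    fit <- fit_curve_points(pts$pressure, pts$y, kind, weights = w)
    return(fit$coef)
  }
  cfs <- purrr::map(series_list, function(s) {
    fit <- fit_arctangent(s)
    if (is.null(fit$params)) return(NULL)
    unlist(fit$params)
  })
  cfs <- purrr::compact(cfs)
  if (length(cfs) == 0L) return(NULL)
  colMeans(do.call(rbind, cfs))
}

curve_value_from_coef <- function(coef, kind, pressure) {
  if (is.null(coef)) return(rep(NA_real_, length(pressure)))
  if (kind == "distensibility" && !"Am" %in% names(coef)) {
    params <- arctan_params(1, coef[["P0"]], coef[["P1"]])
    return(distensibility_at(params, pressure))
  }
  params <- arctan_params(coef[["Am"]], coef[["P0"]], coef[["P1"]])
  switch(kind,
         area = area_at(params, pressure),
         compliance = compliance_at(params, pressure),
         distensibility = distensibility_at(params, pressure))
}

#' Plot pressure-curve families by age group and location
#'
#' One panel per location: each sample's points (observed areas, or
#' finite-difference empirical compliance/distensibility values) with the
#' fitted group curve per age group overlaid.
#'
#' @inheritParams process_dataset
#' @param curve_kind One of `"area"`, `"compliance"`, `"distensibility"`.
#' @param group_method `"pooled"` (one fit to all of a group's points, the
#'   default) or `"mean_params"` (average of per-sample fitted parameters).
#' @param path Optional file path (png/pdf/svg); when given the figure is
#'   written there with [ggplot2::ggsave()].
#' @param width,height Device size in inches when `path` is given.
#' @return The ggplot object, invisibly when `path` is given.
#' @export
plot_curve_families <- function(records,
                                curve_kind = c("area", "compliance",
                                               "distensibility"),
                                group_method = c("pooled", "mean_params"),
                                pressure_range = c(15, 300),
                                path = NULL, width = 8, height = 6) {
  curve_kind <- match.arg(curve_kind)
  group_method <- match.arg(group_method)
  check_pressure_range(pressure_range)
  parts <- split_series(records)
  meta <- parts$meta
  if (nrow(meta) == 0L) stop("no samples to plot", call. = FALSE)
  pts <- purrr::map2(parts$series, names(parts$series), function(s, id) {
    dplyr::bind_cols(tibble::tibble(sample_id = id),
                     curve_points(s, curve_kind))
  }) |> dplyr::bind_rows() |>
    dplyr::left_join(meta, by = "sample_id")
  p_grid <- seq(pressure_range[1L], pressure_range[2L], length.out = 200L)
  curves <- purrr::map(unique(meta$location), function(loc) {
    purrr::map(unique(meta$age_group), function(ag) {
      ids <- meta$sample_id[meta$location == loc & meta$age_group == ag]
      if (length(ids) == 0L) return(NULL)
      cf <- group_curve_params(parts$series[ids], curve_kind, group_method)
      tibble::tibble(location = loc, age_group = ag, pressure = p_grid,
                     y = curve_value_from_coef(cf, curve_kind, p_grid))
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()
  ylab <- switch(curve_kind,
                 area = expression(Area ~ (mm^2)),
                 compliance = expression(Compliance ~ (mm^2 / mmHg)),
                 distensibility = expression(Distensibility ~ (mmHg^-1)))
  gg <- ggplot2::ggplot(pts, ggplot2::aes(x = .data$pressure, y = .data$y,
                                          colour = .data$age_group)) +
    ggplot2::geom_point(ggplot2::aes(shape = .data$age_group),
                        alpha = 0.5, size = 1.2) +
    ggplot2::geom_line(data = curves,
                       ggplot2::aes(linetype = .data$age_group),
                       linewidth = 0.8, na.rm = TRUE) +
    ggplot2::facet_wrap(~location, scales = "free_y") +
    ggplot2::scale_colour_manual(values = c(young = "#1f77b4",
                                            old = "#d62728"),
                                 na.value = "grey40") +
    ggplot2::labs(x = "Pressure (mmHg)", y = ylab,
                  colour = "Age group", shape = "Age group",
                  linetype = "Age group") +
    ggplot2::theme_bw()
  if (!is.null(path)) {
    ggplot2::ggsave(path, gg, width = width, height = height, dpi = 150)
    return(invisible(gg))
  }
  gg
}
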