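# Arctangent (Langewouters) pressure-area model: evaluation, analytic
# derivatives, bounded nonlinear fitting and curve maxima.

#' Arctangent pressure-area model parameters
#'
#' Bundle the three parameters of the arctangent (Langewouters) pressure-area
#' relation \deqn{A(P) = A_m \{1/2 + (1/\pi)\,\arctan((P - P_0)/P_1)\}}{
#' A(P) = Am * (1/2 + arctan((P - P0)/P1)/pi)} used to describe an arterial
#' segment under quasi-static inflation.
#'
#' @param Am Maximal (asymptotic) lumen cross-sectional area, mm^2. Must be
#'   positive.
#' @param P0 Pressure at which compliance is maximal, mmHg. Finite; may lie
#'   outside the measured pressure grid.
#' @param P1 Half-width pressure, mmHg: the offset from `P0` at which
#'   compliance has fallen to half its maximum. Must be positive.
#'
#' @return An object of class `arctan_params`: a named list with elements
#'   `Am`, `P0`, `P1`.
#' @examples
#' p <- arctan_params(Am = 100, P0 = 100, P1 = 50)
#' area_at(p, 100) # = Am/2 at P0
#' @export
arctan_params <- function(Am, P0, P1) {
  for (nm in c("Am", "P0", "P1")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop("`", nm, "` must be a single finite number", call. = FALSE)
    }
  }
  if (Am <= 0) stop("`Am` must be > 0 (maximal area, mm^2)", call. = FALSE)
  if (P1 <= 0) stop("`P1` must be > 0 (half-width pressure, mmHg)", call. = FALSE)
  structure(list(Am = Am, P0 = P0, P1 = P1), class = "arctan_params")
}

as_arctan_params <- function(x) {
  if (inherits(x, "arctan_params")) return(x)
  if (is.list(x) && all(c("Am", "P0", "P1") %in% names(x))) {
    return(arctan_params(x$Am, x$P0, x$P1))
  }
  if (is.numeric(x) && length(x) == 3L) {
    nm <- names(x)
    if (!is.null(nm) && all(c("Am", "P0", "P1") %in% nm)) {
      return(arctan_params(x[["Am"]], x[["P0"]], x[["P1"]]))
    }
    return(arctan_params(x[[1L]], x[[2L]], x[[3L]]))
  }
  stop("cannot interpret `params` as arctangent parameters (Am, P0, P1)",
       call. = FALSE)
}

#' @export
print.arctan_params <- function(x, ...) {
  cat(sprintf("Arctangent pressure-area parameters: Am = %.4g mm^2, P0 = %.4g mmHg, P1 = %.4g mmHg\n",
              x$Am, x$P0, x$P1))
  invisible(x)
}

#' Evaluate the arctangent pressure-area curve
#'
#' @param params An [arctan_params()] object (or coercible list/vector).
#' @param pressure Pressure(s), mmHg. Vectorised.
#' @return Lumen area(s), mm^2, strictly between 0 and `Am` and strictly
#'   increasing in pressure.
#' @examples
#' area_at(arctan_params(3313, 100, 58.6), 120)
#' @export
area_at <- function(params, pressure) {
  params <- as_arctan_params(params)
  stopifnot(is.numeric(pressure))
  params$Am * (0.5 + atan((pressure - params$P0) / params$P1) / pi)
}

#' Analytic area compliance of the arctangent model
#'
#' Compliance is the derivative of the pressure-area curve,
#' \eqn{C_A(P) = (A_m/(\pi P_1)) / (1 + ((P-P_0)/P_1)^2)}: a Lorentzian peak
#' centred at `P0` with maximum `Am/(pi * P1)`.
#'
#' @inheritParams area_at
#' @return Compliance value(s), mm^2/mmHg (always positive).
#' @examples
#' compliance_at(arctan_params(3313, 100, 58.6), 100) # maximum, Am/(pi*P1)
#' @export
compliance_at <- function(params, pressure) {
  params <- as_arctan_params(params)
  stopifnot(is.numeric(pressure))
  z <- (pressure - params$P0) / params$P1
  (params$Am / (pi * params$P1)) / (1 + z^2)
}

#' Analytic area distensibility of the arctangent model
#'
#' Distensibility is relative compliance, \eqn{D_A(P) = C_A(P)/A(P)}
#' (1/mmHg). Note `Am` cancels in the ratio: distensibility depends on
#' `P0` and `P1` only.
#'
#' @inheritParams area_at
#' @return Distensibility value(s), 1/mmHg (always positive).
#' @examples
#' p <- arctan_params(100, 100, 58.6)
#' distensibility_at(p, 100) # = 2/(pi*P1), independent of Am
#' @export
distensibility_at <- function(params, pressure) {
  compliance_at(params, pressure) / area_at(params, pressure)
}

#' Locate the distensibility maximum over a pressure range
#'
#' Distensibility has no closed-form argmax; it is located by a dense grid
#' search (0.1 mmHg spacing) over the range followed by local refinement
#' with [stats::optimize()].
#'
#' @inheritParams area_at
#' @param pressure_range Length-2 numeric, increasing, mmHg.
#' @return Named list with `pressure` (mmHg) and `value` (1/mmHg).
#' @export
max_distensibility <- function(params, pressure_range = c(15, 300)) {
  params <- as_arctan_params(params)
  check_pressure_range(pressure_range)
  grid <- seq(pressure_range[1L], pressure_range[2L], by = 0.1)
  dv <- distensibility_at(params, grid)
  i <- which.max(dv)
  lo <- grid[max(1L, i - 1L)]
  hi <- grid[min(length(grid), i + 1L)]
  if (hi > lo) {
    opt <- stats::optimize(function(p) distensibility_at(params, p),
                           interval = c(lo, hi), maximum = TRUE,
                           tol = 1e-8)
    if (opt$objective >= dv[i]) {
      return(list(pressure = opt$maximum, value = opt$objective))
    }
  }
  list(pressure = grid[i], value = dv[i])
}

check_pressure_range <- function(pressure_range) {
  if (!is.numeric(pressure_range) || length(pressure_range) != 2L ||
      anyNA(pressure_range) || pressure_range[1L] >= pressure_range[2L]) {
    stop("`pressure_range` must be an increasing numeric pair (mmHg)",
         call. = FALSE)
  }
  invisible(pressure_range)
}

#' Per-sample summary metrics of a fitted pressure-area curve
#'
#' Computes the quantities compared between age groups and locations:
#' maximal area (`Am`), maximal compliance (`Am/(pi*P1)` at `P0`, evaluated
#' at the nearest range endpoint when `P0` falls outside the measured
#' range), and maximal distensibility with its pressure (numeric maximum
#' over the range).
#'
#' @inheritParams max_distensibility
#' @return One-row [tibble::tibble()] with columns `max_area_mm2`,
#'   `max_compliance_mm2_mmHg`, `p_at_max_compliance_mmHg`,
#'   `max_distensibility_per_mmHg`, `p_at_max_distensibility_mmHg`.
#' @examples
#' summary_metrics(arctan_params(3313, 100, 58.6))
#' @export
summary_metrics <- function(params, pressure_range = c(15, 300)) {
  params <- as_arctan_params(params)
  check_pressure_range(pressure_range)
  p_c <- min(max(params$P0, pressure_range[1L]), pressure_range[2L])
  d <- max_distensibility(params, pressure_range)
  tibble::tibble(
    max_area_mm2 = params$Am,
    max_compliance_mm2_mmHg = compliance_at(params, p_c),
    p_at_max_compliance_mmHg = p_c,
    max_distensibility_per_mmHg = d$value,
    p_at_max_distensibility_mmHg = d$pressure
  )
}

# Data-driven starting values for the arctangent fit: Am slightly above the
# largest observed area, P0 at the pressure whose area is nearest Am0/2,
# P1 half the inter-quartile width of the pressure grid.
arctan_start <- function(pressures, areas) {
  Am0 <- 1.05 * max(areas)
  P00 <- pressures[which.min(abs(areas - Am0 / 2))]
  q <- stats::quantile(unique(pressures), c(0.25, 0.75), names = FALSE)
  P10 <- max((q[2L] - q[1L]) / 2, 1e-2)
  c(Am = unname(Am0), P0 = unname(P00), P1 = unname(P10))
}

# Bounded Levenberg-Marquardt fit of the arctangent model to (P, A) points.
# `weights` are fixed case weights (used by the group-comparison layer for
# a proportional error model); the weighted RSS is reported when given.
# Falls back over a small ladder of P1 starting values if the data-driven
# start fails.
fit_arctan_points <- function(pressures, areas, weights = NULL,
                              min_points = 5L) {
  stopifnot(is.numeric(pressures), is.numeric(areas),
            length(pressures) == length(areas))
  n <- length(areas)
  n_distinct <- length(unique(pressures))
  empty <- list(params = NULL, rss = NA_real_, r_squared = NA_real_,
                n_points = n, converged = FALSE)
  if (n_distinct < min_points) {
    return(c(empty, list(status = "insufficient_data")))
  }
  if (any(!is.finite(areas)) || any(areas <= 0)) {
    stop("areas must be positive and finite", call. = FALSE)
  }
  if (is.null(weights)) weights <- rep(1, n)
  tss <- sum(weights * (areas - stats::weighted.mean(areas, weights))^2)
  if (tss <= .Machine$double.eps * sum(weights * areas^2)) {
    return(c(empty, list(status = "insufficient_signal")))
  }
  max_a <- max(areas)
  lower <- c(Am = 1e-8, P0 = -1000, P1 = 1e-8)
  upper <- c(Am = 10 * max_a, P0 = 1000, P1 = 1e4)
  dat <- data.frame(.P = pressures, .A = areas, .w = weights)
  starts <- list(arctan_start(pressures, areas))
  for (p1 in c(10, 25, 50, 100, 250)) {
    s <- starts[[1L]]
    s[["P1"]] <- p1
    starts <- c(starts, list(s))
  }
  best <- NULL
  for (st in starts) {
    fit <- try(suppressWarnings(minpack.lm::nlsLM(
      .A ~ Am * (0.5 + atan((.P - P0) / P1) / pi),
      data = dat, start = as.list(st), weights = .w,
      lower = lower, upper = upper,
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-10)
    )), silent = TRUE)
    if (inherits(fit, "try-error")) next
    rss <- sum(weights * stats::residuals(fit)^2)
    if (is.null(best) || rss < best$rss) {
      best <- list(fit = fit, rss = rss, start = st)
    }
    if (!is.null(best) && identical(st, starts[[1L]])) break
  }
  if (is.null(best)) {
    return(c(empty, list(status = "failed")))
  }
  cf <- stats::coef(best$fit)
  conv <- isTRUE(best$fit$convInfo$isConv)
  list(
    params = arctan_params(cf[["Am"]], cf[["P0"]], cf[["P1"]]),
    rss = best$rss,
    r_squared = 1 - best$rss / tss,
    n_points = n,
    converged = conv,
    status = if (conv) "converged" else "not_converged"
  )
}

#' Fit the arctangent model to a pressure-area series
#'
#' Bounded nonlinear least squares (Levenberg-Marquardt via
#' \pkg{minpack.lm}) of the arctangent pressure-area model to one sample's
#' series. Starting values are data-driven (see Details); bounds keep the
#' optimiser in the identifiable regime (`Am` in (0, 10 x max observed
#' area], `P1` in (0, 1e4], `P0` in \[-1000, 1000\] mmHg) while allowing the
#' compliance peak to lie outside the measured grid.
#'
#' @details Starting values: `Am` = 1.05 x the largest observed area, `P0` =
#' the pressure whose area is nearest half that, `P1` = half the
#' inter-quartile width of the pressure grid. A series with fewer than
#' `min_points` distinct pressures (default 5, three parameters plus two) is
#' refused: ruptured samples have truncated grids and a floor prevents
#' near-interpolation pseudo-fits. A series with no area signal (all areas
#' equal) is flagged `insufficient_signal` rather than given spurious
#' parameters. R-squared is `1 - RSS/TSS` with TSS about the mean observed
#' area; a non-converged optimiser result is returned flagged, never
#' silently.
#'
#' @param series A `pa_series` from [build_series()], or a data frame with
#'   columns `pressure_mmHg` and `area_mm2`.
#' @param min_points Minimum number of distinct pressures required.
#' @return An object of class `arctan_fit`: list with `params`
#'   ([arctan_params()] or `NULL`), `rss` (mm^4), `r_squared`, `n_points`,
#'   `converged`, `status` (one of `"converged"`, `"not_converged"`,
#'   `"insufficient_data"`, `"insufficient_signal"`, `"failed"`).
#' @examples
#' p <- arctan_params(1000, 110, 40)
#' grid <- protocol_pressure_grid()
#' s <- new_pa_series("s1", grid, area_at(p, grid))
#' fit_arctangent(s)$params
#' @export
fit_arctangent <- function(series, min_points = 5L) {
  xy <- series_points(series)
  n_distinct <- length(unique(xy$pressure))
  if (n_distinct < min_points) {
    rlang::abort(paste0("need at least ", min_points,
                        " distinct pressures to fit (got ", n_distinct, ")"),
                 class = "vasofit_insufficient_data")
  }
  res <- fit_arctan_points(xy$pressure, xy$area, min_points = min_points)
  structure(res, class = "arctan_fit")
}

#' @export
print.arctan_fit <- function(x, ...) {
  cat("Arctangent model fit (", x$status, ", n = ", x$n_points, ")\n", sep = "")
  if (!is.null(x$params)) {
    print(x$params)
    cat(sprintf("  RSS = %.4g mm^4, R^2 = %.4f\n", x$rss, x$r_squared))
  }
  invisible(x)
}

# Extract (pressure, area) points from a pa_series or plain data frame.
series_points <- function(series) {
  if (inherits(series, "pa_series")) {
    return(list(pressure = series$pressures, area = series$areas))
  }
  if (is.data.frame(series) &&
      all(c("pressure_mmHg", "area_mm2") %in% names(series))) {
    return(list(pressure = series$pressure_mmHg, area = series$area_mm2))
  }
  stop("`series` must be a pa_series or a data frame with pressure_mmHg/area_mm2",
       call. = FALSE)
}
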