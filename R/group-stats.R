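# Age-group comparison of whole curves (nested extra-sum-of-squares
# F-tests) and of summary metrics (two-way ANOVA with Bonferroni-adjusted
# location contrasts).

# Fit the analytic curve of the requested kind to pooled (P, y) points.
# area: 3-parameter arctangent on (pressure, area).
# compliance: 3-parameter Lorentzian C(P) = (Am/(pi P1)) / (1 + ((P-P0)/P1)^2).
# distensibility: D(P) = C(P)/A(P); Am cancels, leaving 2 parameters.
fit_curve_points <- function(pressure, y, kind, weights = NULL,
                             extra_starts = NULL) {
  n <- length(y)
  if (is.null(weights)) weights <- rep(1, n)
  dat <- data.frame(.P = pressure, .y = y, .w = weights)
  if (kind == "area") {
    res <- fit_arctan_points(pressure, y, weights = weights)
    return(list(rss = res$rss, coef = if (is.null(res$params)) NULL else
      unlist(res$params), n_par = 3L, converged = res$converged))
  }
  peak_p <- pressure[which.max(y)]
  q <- stats::quantile(unique(pressure), c(0.25, 0.75), names = FALSE)
  width0 <- max((q[2L] - q[1L]) / 2, 1)
  if (kind == "compliance") {
    form <- .y ~ (Am / (pi * P1)) / (1 + ((.P - P0) / P1)^2)
    starts <- list(c(Am = max(y) * pi * width0, P0 = peak_p, P1 = width0))
    for (w in c(20, 50, 120)) {
      starts <- c(starts, list(c(Am = max(y) * pi * w, P0 = peak_p, P1 = w)))
    }
    lower <- c(Am = 1e-10, P0 = -1000, P1 = 1e-8)
    upper <- c(Am = Inf, P0 = 1000, P1 = 1e4)
    n_par <- 3L
  } else if (kind == "distensibility") {
    form <- .y ~ (1 / (pi * P1)) / ((1 + ((.P - P0) / P1)^2) *
                                      (0.5 + atan((.P - P0) / P1) / pi))
    starts <- list(c(P0 = peak_p, P1 = width0))
    for (w in c(20, 50, 120)) starts <- c(starts, list(c(P0 = peak_p, P1 = w)))
    lower <- c(P0 = -1000, P1 = 1e-8)
    upper <- c(P0 = 1000, P1 = 1e4)
    n_par <- 2L
  } else {
    stop("unknown curve kind: ", kind, call. = FALSE)
  }
  if (!is.null(extra_starts)) starts <- c(list(extra_starts), starts)
  best <- NULL
  for (st in starts) {
    fit <- try(suppressWarnings(minpack.lm::nlsLM(
      form, data = dat, start = as.list(st), weights = .w,
      lower = lower, upper = upper,
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-10)
    )), silent = TRUE)
    if (inherits(fit, "try-error")) next
    rss <- sum(weights * stats::residuals(fit)^2)
    if (is.null(best) || rss < best$rss) {
      best <- list(rss = rss, coef = stats::coef(fit),
                   converged = isTRUE(fit$convInfo$isConv))
    }
  }
  if (is.null(best)) {
    return(list(rss = NA_real_, coef = NULL, n_par = n_par, converged = FALSE))
  }
  c(best, list(n_par = n_par))
}

# Assemble the per-sample points entering a curve comparison.
curve_points <- function(series, kind) {
  if (kind == "area") {
    xy <- series_points(series)
    return(tibble::tibble(pressure = xy$pressure, y = xy$area))
  }
  emp <- empirical_compliance(series)
  y <- if (kind == "compliance") emp$compliance_mm2_mmHg else
    emp$distensibility_per_mmHg
  tibble::tibble(pressure = emp$pressure_mmHg, y = y)
}

#' Nested extra-sum-of-squares F-test for a group effect on a curve
#'
#' Tests whether one curve describes all samples as well as one curve per
#' group. For the pressure-area curve the 3-parameter arctangent model is
#' fitted to all points pooled (RSS_pooled) and separately per group
#' (RSS_separate = sum of group RSS); for compliance and distensibility the
#' analytic derived forms are fitted to finite-difference empirical points
#' from [empirical_compliance()] (the distensibility form has 2 free
#' parameters because the area asymptote cancels in C/A). Then
#' \deqn{F = \frac{(RSS_p - RSS_s)/(p(k-1))}{RSS_s/(N - pk)}}{
#' F = ((RSS_p - RSS_s)/(p*(k-1))) / (RSS_s/(N - p*k))}
#' with p parameters per curve, k groups and N points, referred to the F
#' distribution.
#'
#' @param series_list List of `pa_series`, one per sample.
#' @param groups Vector of group labels, one per series (e.g. age group);
#'   at least 2 samples per group.
#' @param curve_kind One of `"area"`, `"compliance"`, `"distensibility"`.
#' @param error_model `"proportional"` (default) weights each point by
#'   `1/y^2`, the correct error model when measurement noise scales with
#'   the measured value, as ultrasound caliper noise does — this keeps the
#'   test calibrated across the large dynamic range of arterial areas.
#'   `"additive"` uses unweighted residuals. Weights are fixed from the
#'   observed values and shared between pooled and group fits, so the
#'   models stay exactly nested.
#' @return One-row tibble: `curve_kind`, `n_points`, `n_groups`,
#'   `rss_pooled`, `rss_separate`, `df_num`, `df_den`, `f_statistic`,
#'   `p_value`, `degenerate`. When the separate-fit residuals are
#'   essentially zero (noise-free data), the comparison is reported as
#'   degenerate with `p_value = 1` rather than a spurious effect.
#' @examples
#' sim <- gen_inflation_dataset(n_young = 3, n_old = 3, seed = 2)
#' one_loc <- sim$records[sim$records$location == "common_carotid", ]
#' parts <- split(one_loc, one_loc$sample_id)
#' series <- lapply(parts, build_series)
#' grp <- vapply(parts, function(d) d$age_group[1], character(1))
#' nested_f_test(series, grp, "area")
#' @export
nested_f_test <- function(series_list, groups,
                          curve_kind = c("area", "compliance", "distensibility"),
                          error_model = c("proportional", "additive")) {
  curve_kind <- match.arg(curve_kind)
  error_model <- match.arg(error_model)
  if (length(series_list) != length(groups)) {
    stop("`groups` must label each series", call. = FALSE)
  }
  groups <- as.character(groups)
  tab <- table(groups)
  if (length(tab) < 2L) stop("need at least 2 groups", call. = FALSE)
  if (any(tab < 2L)) {
    stop("each group needs at least 2 samples", call. = FALSE)
  }
  pts <- purrr::map(series_list, curve_points, kind = curve_kind)
  per_sample_n <- vapply(pts, nrow, integer(1L))
  all_pts <- dplyr::bind_rows(pts)
  grp_of_point <- rep(groups, per_sample_n)
  w <- if (error_model == "proportional") 1 / all_pts$y^2 else
    rep(1, nrow(all_pts))
  if (any(!is.finite(w))) {
    stop("proportional error model requires nonzero observed values",
         call. = FALSE)
  }
  k <- length(tab)
  pooled <- fit_curve_points(all_pts$pressure, all_pts$y, curve_kind, w)
  n_par <- pooled$n_par
  N <- nrow(all_pts)
  if (N < n_par * k + 2L) {
    stop("too few pooled points for the nested comparison", call. = FALSE)
  }
  rss_sep <- 0
  sep_ok <- TRUE
  for (g in names(tab)) {
    sel <- grp_of_point == g
    fg <- fit_curve_points(all_pts$pressure[sel], all_pts$y[sel], curve_kind,
                           w[sel], extra_starts = pooled$coef)
    if (!is.finite(fg$rss)) sep_ok <- FALSE else rss_sep <- rss_sep + fg$rss
  }
  tss <- sum(w * (all_pts$y - stats::weighted.mean(all_pts$y, w))^2)
  degenerate <- !sep_ok || !is.finite(pooled$rss) || rss_sep <= 1e-12 * tss
  if (degenerate) {
    return(tibble::tibble(
      curve_kind = curve_kind, n_points = N, n_groups = k,
      rss_pooled = pooled$rss, rss_separate = rss_sep,
      df_num = n_par * (k - 1L), df_den = N - n_par * k,
      f_statistic = NA_real_, p_value = 1, degenerate = TRUE
    ))
  }
  # the pooled curve is a special case of the separate curves; a separate
  # fit stuck in a worse optimum would violate nesting, so clamp at 0
  extra <- max(pooled$rss - rss_sep, 0)
  df_num <- n_par * (k - 1L)
  df_den <- N - n_par * k
  f_stat <- (extra / df_num) / (rss_sep / df_den)
  tibble::tibble(
    curve_kind = curve_kind, n_points = N, n_groups = k,
    rss_pooled = pooled$rss, rss_separate = rss_sep,
    df_num = df_num, df_den = df_den,
    f_statistic = f_stat,
    p_value = stats::pf(f_stat, df_num, df_den, lower.tail = FALSE),
    degenerate = FALSE
  )
}

#' Compare age-group curves at every location of a dataset
#'
#' Convenience wrapper running [nested_f_test()] per location (and
#' requested curve kind) on a long-format inflation record table.
#'
#' @inheritParams process_dataset
#' @inheritParams nested_f_test
#' @param curve_kinds Curve kinds to compare.
#' @return Tibble of [nested_f_test()] rows with a leading `location`
#'   column.
#' @export
compare_age_groups <- function(records,
                               curve_kinds = c("area", "compliance",
                                               "distensibility"),
                               error_model = c("proportional", "additive")) {
  error_model <- match.arg(error_model)
  curve_kinds <- match.arg(curve_kinds, several.ok = TRUE)
  parts <- split_series(records)
  meta <- parts$meta
  out <- purrr::map(unique(meta$location), function(loc) {
    ids <- meta$sample_id[meta$location == loc]
    grp <- meta$age_group[meta$location == loc]
    purrr::map(curve_kinds, function(kind) {
      res <- nested_f_test(parts$series[ids], grp, kind,
                           error_model = error_model)
      dplyr::bind_cols(tibble::tibble(location = loc), res)
    }) |> dplyr::bind_rows()
  })
  dplyr::bind_rows(out)
}

#' Bonferroni adjustment over an explicit family size
#'
#' `p_adj = min(1, p * family_size)`. Unlike [stats::p.adjust()], the
#' family size may exceed the number of p-values supplied (e.g. when only
#' a subset of all pairwise location contrasts is of interest but the
#' family is all `choose(k, 2)` of them).
#'
#' @param p_values Numeric vector of raw p-values in \[0, 1\].
#' @param family_size Number of comparisons in the family; at least
#'   `length(p_values)`.
#' @return Adjusted p-values, same length as `p_values`.
#' @examples
#' bonferroni(0.01, 21) # 7 locations -> choose(7, 2) = 21 pairs
#' @export
bonferroni <- function(p_values, family_size = length(p_values)) {
  if (!is.numeric(p_values) || anyNA(p_values) ||
      any(p_values < 0 | p_values > 1)) {
    stop("`p_values` must be numbers in [0, 1]", call. = FALSE)
  }
  if (family_size < length(p_values)) {
    stop("`family_size` must be at least the number of p-values", call. = FALSE)
  }
  pmin(1, p_values * family_size)
}

# Greedy compact-letter assignment from a symmetric matrix of adjusted
# pairwise p-values: groups not significantly different share a letter.
significance_letters <- function(p_matrix, alpha = 0.05) {
  stopifnot(is.matrix(p_matrix), nrow(p_matrix) == ncol(p_matrix))
  nms <- rownames(p_matrix)
  classes <- list()
  for (g in nms) {
    placed <- FALSE
    for (i in seq_along(classes)) {
      if (all(p_matrix[g, classes[[i]]] > alpha, na.rm = TRUE)) {
        classes[[i]] <- c(classes[[i]], g)
        placed <- TRUE
      }
    }
    if (!placed) classes[[length(classes) + 1L]] <- g
  }
  letters_out <- stats::setNames(rep("", length(nms)), nms)
  for (i in seq_along(classes)) {
    for (g in classes[[i]]) {
      letters_out[g] <- paste0(letters_out[g], letters[i])
    }
  }
  letters_out
}

# Shared machinery for fixed-effects two-way ANOVA per outcome with
# Bonferroni-adjusted pairwise location contrasts (SPSS-style type-III
# sums of squares under sum-to-zero contrasts).
fixed_anova_one <- function(dat, outcome, alpha, include_interaction,
                            posthoc = TRUE) {
  y <- dat[[outcome]]
  keep <- is.finite(y)
  dat <- dat[keep, , drop = FALSE]
  y <- y[keep]
  res_empty <- list(effects = NULL, posthoc = NULL, letters = NULL,
                    degenerate = FALSE, note = NA_character_)
  if (length(unique(dat$age_group)) < 2L || length(unique(dat$location)) < 2L) {
    res_empty$degenerate <- TRUE
    res_empty$note <- "needs >= 2 levels of age_group and location"
    return(res_empty)
  }
  if (stats::var(y) == 0) {
    res_empty$degenerate <- TRUE
    res_empty$note <- "zero between-group variance"
    return(res_empty)
  }
  dat$age_group <- factor(dat$age_group)
  dat$location <- factor(dat$location)
  form <- if (include_interaction) {
    stats::reformulate(c("age_group", "location", "age_group:location"),
                       response = outcome)
  } else {
    stats::reformulate(c("age_group", "location"), response = outcome)
  }
  old <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(old), add = TRUE)
  mod <- stats::lm(form, data = dat)
  atab <- tryCatch(car::Anova(mod, type = 3),
                   error = function(e) NULL)
  if (is.null(atab)) {
    res_empty$degenerate <- TRUE
    res_empty$note <- "type-III ANOVA not estimable"
    return(res_empty)
  }
  adf <- as.data.frame(atab)
  terms_keep <- setdiff(rownames(adf), c("(Intercept)", "Residuals"))
  effects <- tibble::tibble(
    outcome = outcome,
    term = terms_keep,
    df = adf[terms_keep, "Df"],
    df_resid = adf["Residuals", "Df"],
    f_statistic = adf[terms_keep, "F value"],
    p_value = adf[terms_keep, "Pr(>F)"]
  )
  ph <- if (posthoc) location_posthoc(mod, dat, alpha) else
    list(table = NULL, letters = NULL)
  list(effects = effects, posthoc = ph$table, letters = ph$letters,
       degenerate = FALSE, note = NA_character_)
}

# Pairwise location contrasts on estimated marginal means; raw p-values
# from emmeans, Bonferroni applied over all choose(k, 2) pairs.
location_posthoc <- function(mod, dat, alpha) {
  k <- length(levels(dat$location))
  fam <- choose(k, 2)
  emm <- suppressMessages(emmeans::emmeans(mod, "location"))
  prs <- as.data.frame(suppressMessages(
    emmeans::contrast(emm, method = "pairwise", adjust = "none")))
  tab <- tibble::tibble(
    contrast = prs$contrast,
    estimate = prs$estimate,
    se = prs$SE,
    df = prs$df,
    p_raw = prs$p.value,
    p_adj = bonferroni(prs$p.value, fam)
  )
  lv <- levels(dat$location)
  pm <- matrix(NA_real_, k, k, dimnames = list(lv, lv))
  sides <- strsplit(tab$contrast, " - ", fixed = TRUE)
  for (i in seq_along(sides)) {
    a <- sides[[i]][1L]; b <- sides[[i]][2L]
    pm[a, b] <- pm[b, a] <- tab$p_adj[i]
  }
  list(table = tab, letters = significance_letters(pm, alpha))
}

#' Two-way ANOVA of inflation summary metrics
#'
#' Compares per-sample summary metrics (maximal area, maximal compliance,
#' maximal distensibility) between age groups and among locations with a
#' fixed-effects two-way ANOVA per outcome (type-III sums of squares under
#' sum-to-zero contrasts, the convention of mainstream point-and-click
#' statistics packages), followed by pairwise location contrasts on
#' estimated marginal means with Bonferroni adjustment over all
#' `choose(k, 2)` pairs.
#'
#' @param metrics Tibble from [process_dataset()] (or any data frame with
#'   `age_group`, `location` and the outcome columns).
#' @param outcomes Outcome columns to analyse.
#' @param alpha Significance threshold (default 0.05).
#' @param include_interaction Include the age x location interaction term.
#' @return Object of class `vasofit_anova`: list with `effects` (tibble of
#'   F-tests per outcome and term), `posthoc` (pairwise location table per
#'   outcome), `letters` (compact letter display per outcome),
#'   `degenerate` (per-outcome flags with notes), `alpha`.
#' @export
anova_summary_metrics <- function(metrics,
                                  outcomes = c("max_area_mm2",
                                               "max_compliance_mm2_mmHg",
                                               "max_distensibility_per_mmHg"),
                                  alpha = 0.05,
                                  include_interaction = TRUE) {
  stopifnot(is.data.frame(metrics))
  missing_cols <- setdiff(c("age_group", "location", outcomes), names(metrics))
  if (length(missing_cols) > 0L) {
    stop("metrics table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  res <- purrr::map(outcomes, function(oc) {
    fixed_anova_one(metrics, oc, alpha, include_interaction)
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

#' @export
print.vasofit_anova <- function(x, ...) {
  cat("Fixed-effects ANOVA (alpha =", x$alpha, ")\n")
  if (!is.null(x$effects) && nrow(x$effects) > 0L) {
    print(as.data.frame(x$effects), row.names = FALSE)
  }
  deg <- x$degenerate[x$degenerate$degenerate, , drop = FALSE]
  if (nrow(deg) > 0L) {
    cat("Degenerate outcomes:",
        paste(deg$outcome, "-", deg$note, collapse = "; "), "\n")
  }
  invisible(x)
}

#' Null calibration of the age-effect nested F-test
#'
#' Simulates the no-effect condition — every sample in both age groups
#' generated from one shared parameter triple, with multiplicative
#' diameter measurement noise only — and returns the nested F-test
#' p-values, giving an empirical type-I error rate at any threshold. The
#' default null uses the young proximal-aorta profile parameters and the
#' study's 6 young / 14 old design.
#'
#' @param n_sims Number of simulated datasets.
#' @param seed Master seed; per-replicate seeds are drawn from it, so the
#'   whole calibration is reproducible.
#' @param location Profile row (of [default_vessel_profiles()], young age
#'   group) supplying the shared parameters.
#' @param n_young,n_old Samples per group.
#' @param diameter_noise Multiplicative diameter noise SD (fraction).
#' @param curve_kind Curve the comparison is run on.
#' @param error_model Passed to [nested_f_test()].
#' @param alpha Threshold at which the rejection rate is reported.
#' @return List with `p_values` (length `n_sims`), `rejection_rate` at
#'   `alpha`, `alpha`, `n_sims`.
#' @examples
#' f_test_null_calibration(n_sims = 20, seed = 1)$rejection_rate
#' @export
f_test_null_calibration <- function(n_sims = 1000, seed = 1,
                                    location = "proximal_aorta",
                                    n_young = 6, n_old = 14,
                                    diameter_noise = 0.02,
                                    curve_kind = "area",
                                    error_model = "proportional",
                                    alpha = 0.05) {
  base <- default_vessel_profiles()
  base <- base[base$location == location & base$age_group == "young", ]
  if (nrow(base) != 1L) stop("unknown location: ", location, call. = FALSE)
  # identical parameters in both groups, no between-horse spread: the
  # only randomness left is the measurement noise
  null_profiles <- dplyr::bind_rows(
    dplyr::mutate(base, age_group = "young"),
    dplyr::mutate(base, age_group = "old")
  ) |>
    dplyr::mutate(sd_Am = 0, sd_P0 = 0, sd_P1 = 0,
                  diameter_noise = .env$diameter_noise)
  seeds <- withr::with_seed(seed,
                            sample.int(.Machine$integer.max - 1L, n_sims))
  p_values <- vapply(seq_len(n_sims), function(i) {
    sim <- gen_inflation_dataset(null_profiles, n_young = n_young,
                                 n_old = n_old, seed = seeds[i])
    parts <- split_series(sim$records)
    nested_f_test(parts$series, parts$meta$age_group, curve_kind,
                  error_model = error_model)$p_value
  }, numeric(1L))
  list(p_values = p_values,
       rejection_rate = mean(p_values <= alpha),
       alpha = alpha, n_sims = n_sims)
}
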