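test_that("bonferroni multiplies by the family size and caps at 1", {
  expect_equal(bonferroni(0.01, 21), 0.21)
  expect_equal(bonferroni(0.5, 6), 1)
  expect_equal(bonferroni(0, 100), 0)
  expect_error(bonferroni(1.2, 5), "\\[0, 1\\]")
  expect_error(bonferroni(c(0.1, 0.2), 1), "family_size")
  withr::with_seed(31, {
    p <- runif(20)
    expect_true(all(bonferroni(p, 25) >= p))
  })
})

test_that("identical groups without noise take the degeneracy path", {
  truth <- arctan_params(1000, 110, 40)
  series <- lapply(1:6, function(i) noise_free_series(truth, sample_id = i))
  res <- nested_f_test(series, rep(c("young", "old"), each = 3), "area")
  expect_true(res$degenerate)
  expect_equal(res$p_value, 1)
})

test_that("a twofold area difference is detected at p < 0.001", {
  withr::with_seed(32, {
    g <- make_group_series(arctan_params(1000, 110, 40),
                           arctan_params(2000, 110, 40),
                           n_young = 6, n_old = 14, noise = 0.02)
    for (kind in c("area", "compliance")) {
      res <- nested_f_test(g$series, g$groups, kind)
      expect_false(res$degenerate)
      expect_lt(res$p_value, 0.001)
    }
  })
})

test_that("pooled residuals never undercut the separate fits", {
  withr::with_seed(33, {
    for (i in 1:8) {
      py <- random_params()
      po <- arctan_params(py$Am * runif(1, 0.8, 1.3), py$P0 + rnorm(1, 0, 15),
                          py$P1 * runif(1, 0.8, 1.3))
      g <- make_group_series(py, po, 3, 4, noise = 0.03)
      kind <- sample(c("area", "compliance", "distensibility"), 1)
      res <- nested_f_test(g$series, g$groups, kind)
      expect_gte(res$rss_pooled, res$rss_separate - 1e-9 * res$rss_pooled)
      expect_gte(res$p_value, 0)
      expect_lte(res$p_value, 1)
    }
  })
})

test_that("undersized groups are refused", {
  truth <- arctan_params(1000, 110, 40)
  series <- lapply(1:3, function(i) noise_free_series(truth, sample_id = i))
  expect_error(nested_f_test(series, c("young", "old", "old"), "area"),
               "at least 2 samples")
  expect_error(nested_f_test(series, rep("young", 3), "area"),
               "at least 2 groups")
})

test_that("F-test decisions agree with a label-permutation test on small samples", {
  # the permutation reference recomputes F under shuffled sample labels;
  # the pooled RSS is label-invariant so only the group fits are redone
  perm_p <- function(series, groups, n_perm, f_obs) {
    pts <- lapply(series, vasofit:::curve_points, kind = "area")
    npts <- vapply(pts, nrow, integer(1))
    all_pts <- dplyr::bind_rows(pts)
    w <- 1 / all_pts$y^2
    pooled <- vasofit:::fit_curve_points(all_pts$pressure, all_pts$y,
                                         "area", w)
    f_for <- function(g) {
      gp <- rep(g, npts)
      rss_sep <- sum(vapply(unique(g), function(lv) {
        sel <- gp == lv
        vasofit:::fit_curve_points(all_pts$pressure[sel], all_pts$y[sel],
                                   "area", w[sel],
                                   extra_starts = pooled$coef)$rss
      }, numeric(1)))
      extra <- max(pooled$rss - rss_sep, 0)
      (extra / 3) / (rss_sep / (nrow(all_pts) - 6))
    }
    f_perm <- vapply(seq_len(n_perm), function(i) f_for(sample(groups)),
                     numeric(1))
    (1 + sum(f_perm >= f_obs, na.rm = TRUE)) / (1 + n_perm)
  }
  withr::with_seed(34, {
    agree <- logical(0)
    base <- arctan_params(500, 110, 50)
    strong <- arctan_params(900, 110, 50)
    for (rep_i in 1:20) {
      effect <- rep_i <= 10
      g <- make_group_series(base, if (effect) strong else base,
                             n_young = 4, n_old = 4, noise = 0.03)
      res <- nested_f_test(g$series, g$groups, "area")
      p_ref <- perm_p(g$series, g$groups, 499, res$f_statistic)
      agree <- c(agree, (res$p_value < 0.05) == (p_ref < 0.05))
    }
    expect_gte(mean(agree), 0.95)
  })
})

test_that("metric ANOVA separates location effects from a null age effect", {
  gen_metrics <- function(age_delta = 0, loc_delta = c(0, 5, 10, 20)) {
    cells <- expand.grid(age_group = c("young", "old"),
                         location = c("a", "b", "c", "d"),
                         rep = 1:3, stringsAsFactors = FALSE)
    cells$max_area_mm2 <- 100 + loc_delta[match(cells$location, letters[1:4])] +
      age_delta * (cells$age_group == "old") + rnorm(nrow(cells), 0, 3)
    tibble::as_tibble(cells)
  }
  withr::with_seed(35, {
    age_p <- vapply(1:200, function(i) {
      an <- anova_summary_metrics(gen_metrics(), outcomes = "max_area_mm2")
      an$effects$p_value[an$effects$term == "age_group"]
    }, numeric(1))
    expect_gte(mean(age_p > 0.05), 0.90)
  })
})

test_that("a huge location separation yields adjusted p < 0.001", {
  withr::with_seed(36, {
    tbl <- tibble::tibble(
      age_group = rep(c("young", "old"), 10),
      location = rep(c("a", "b"), each = 10),
      max_area_mm2 = c(rnorm(10, 100, 2), rnorm(10, 120, 2)) # 10 SDs apart
    )
    an <- anova_summary_metrics(tbl, outcomes = "max_area_mm2",
                                include_interaction = FALSE)
    loc_p <- an$effects$p_value[an$effects$term == "location"]
    expect_lt(loc_p, 0.001)
    expect_true(all(an$posthoc$max_area_mm2$p_adj < 0.001))
    # fully separated locations get distinct letters
    expect_false(an$letters$max_area_mm2[["a"]] ==
                   an$letters$max_area_mm2[["b"]])
  })
})

test_that("constant outcomes are reported degenerate, not tested", {
  tbl <- tibble::tibble(
    age_group = rep(c("young", "old"), 8),
    location = rep(c("a", "b"), each = 8),
    max_area_mm2 = 5
  )
  an <- anova_summary_metrics(tbl, outcomes = "max_area_mm2")
  expect_true(an$degenerate$degenerate[1])
  expect_match(an$degenerate$note[1], "variance")
})

test_that("whole-dataset age comparison returns one row per location and kind", {
  sim <- gen_inflation_dataset(n_young = 3, n_old = 3, seed = 37)
  ct <- compare_age_groups(sim$records, curve_kinds = c("area", "compliance"))
  expect_equal(nrow(ct), 4 * 2)
  expect_true(all(ct$p_value >= 0 & ct$p_value <= 1))
  expect_true(all(ct$df_num == ifelse(ct$curve_kind == "distensibility", 2, 3)))
})
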