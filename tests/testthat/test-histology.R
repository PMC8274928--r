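test_that("frame means respect the measurement domain", {
  expect_equal(mean_of_frames(c(10, 12, 14, 16, 18)), 14)
  expect_equal(mean_of_frames(rep(7, 5)), 7)
  expect_error(mean_of_frames(c(-1, 5, 5, 5, 5)), "outside")
  expect_error(mean_of_frames(c(101, 5, 5, 5, 5)), "outside")
  expect_equal(mean_of_frames(c(500, 700), domain = c(0, Inf)), 600)
})

test_that("overall area % is the thickness-weighted convex combination", {
  expect_equal(overall_area_percent(40, 600, 10, 400), 28)
  # convexity: equal layer values pass through unchanged
  withr::with_seed(41, {
    for (i in 1:10) {
      x <- runif(1, 0, 100)
      t1 <- runif(1, 100, 2000); t2 <- runif(1, 100, 2000)
      expect_equal(overall_area_percent(x, t1, x, t2), x)
      p1 <- runif(1, 0, 100); p2 <- runif(1, 0, 100)
      ov <- overall_area_percent(p1, t1, p2, t2)
      expect_gte(ov, min(p1, p2))
      expect_lte(ov, max(p1, p2))
      # swapping layers with their weights leaves the result unchanged
      expect_equal(ov, overall_area_percent(p2, t2, p1, t1))
    }
  })
  # single-layer degenerate case (proximal aorta)
  expect_equal(overall_area_percent(35, 800, NA, 0), 35)
  expect_error(overall_area_percent(35, 0, 10, 0), "positive total")
  expect_error(overall_area_percent(120, 600, 10, 400), "\\[0, 100\\]")
})

test_that("aggregation follows the means-first order, which matters", {
  # counterexample: frame-varying thickness makes frame-wise weighting
  # differ from the protocol's means-first order
  mk_rows <- function(layer, pct, th) {
    tibble::tibble(horse_id = "h01", age_group = "young",
                   location = "common_carotid", layer = layer,
                   stain = "elastin", frame_index = 1:2,
                   area_pct = pct, thickness_um = th)
  }
  rec <- dplyr::bind_rows(
    mk_rows(1, c(10, 50), c(100, 900)),
    mk_rows(2, c(80, 80), c(900, 100))
  )
  # fill remaining stains so the schema is complete
  other <- dplyr::bind_rows(lapply(c("sma", "col1", "col3"), function(st) {
    dplyr::mutate(rec, stain = st)
  }))
  agg <- aggregate_histology(dplyr::bind_rows(rec, other))
  means_first <- overall_area_percent(mean(c(10, 50)), mean(c(100, 900)),
                                      80, mean(c(900, 100)))
  frame_wise <- mean(c(overall_area_percent(10, 100, 80, 900),
                       overall_area_percent(50, 900, 80, 100)))
  expect_equal(agg$elastin_pct, means_first)
  expect_false(isTRUE(all.equal(means_first, frame_wise)))
})

test_that("generated slides aggregate to the expected layer structure", {
  h <- gen_histology_dataset(n_young = 3, n_old = 4, seed = 42)
  agg <- aggregate_histology(h)
  expect_equal(nrow(agg), 7 * 7)
  # proximal aorta: single layer, thickness not assessed
  pa <- agg[agg$location == "proximal_aorta", ]
  expect_true(all(pa$n_layers == 1))
  expect_true(all(is.na(pa$imt_um)))
  # muscular arteries always split into two layers
  cc <- agg[agg$location == "common_carotid", ]
  expect_true(all(cc$n_layers == 2))
  expect_true(all(is.finite(cc$imt_um) & cc$imt_um > 0))
  expect_true(all(agg$elastin_pct >= 0 & agg$elastin_pct <= 100, na.rm = TRUE))
})

test_that("mixed-model F collapses to the fixed ANOVA at zero horse variance", {
  # horse means constructed exactly equal within age group, so the REML
  # variance estimate sits on the zero boundary
  withr::with_seed(43, {
    d <- expand.grid(horse_id = sprintf("h%02d", 1:20), location = c("a", "b"),
                     stringsAsFactors = FALSE)
    d$age_group <- ifelse(as.integer(sub("h", "", d$horse_id)) <= 6,
                          "young", "old")
    delta <- rnorm(20, 0, 50)
    i <- match(d$horse_id, sprintf("h%02d", 1:20))
    d$imt_um <- 1500 + 200 * (d$location == "b") +
      100 * (d$age_group == "old") +
      ifelse(d$location == "a", delta[i], -delta[i])
    d <- tibble::as_tibble(d)
    ha <- histo_anova(d, outcomes = "imt_um")
    old <- options(contrasts = c("contr.sum", "contr.poly"))
    on.exit(options(old), add = TRUE)
    ref <- car::Anova(stats::lm(imt_um ~ age_group + location, data = d),
                      type = 3)
    for (term in c("age_group", "location")) {
      expect_equal(ha$effects$f_statistic[ha$effects$term == term],
                   ref[term, "F value"], tolerance = 1e-8)
    }
  })
})

test_that("an age shift confined to thickness is detected with high power", {
  # stains equal across ages; thickness keeps its default age contrast
  prof <- default_histo_profiles()
  for (st in c("elastin", "sma", "col1", "col3")) {
    m <- paste0(st, "_pct"); s <- paste0("sd_", st, "_pct")
    young_vals <- prof[prof$age_group == "young", c(m, s)]
    prof[prof$age_group == "old", c(m, s)] <- young_vals
  }
  withr::with_seed(44, {
    hits <- vapply(1:200, function(i) {
      h <- gen_histology_dataset(prof, n_young = 6, n_old = 14,
                                 seed = sample.int(2^30, 1))
      ha <- histo_anova(aggregate_histology(h), outcomes = "imt_um",
                        posthoc = FALSE)
      p <- ha$effects$p_value[ha$effects$term == "age_group"]
      length(p) == 1 && is.finite(p) && p <= 0.05
    }, logical(1))
    expect_gte(mean(hits), 0.80)
  })
})

test_that("with no simulated effects the age test keeps its nominal size", {
  prof <- default_histo_profiles()
  young <- prof[prof$age_group == "young", ]
  old <- young
  old$age_group <- "old"
  null_prof <- dplyr::bind_rows(young, old)
  withr::with_seed(45, {
    p_vals <- vapply(1:200, function(i) {
      h <- gen_histology_dataset(null_prof, n_young = 6, n_old = 14,
                                 seed = sample.int(2^30, 1))
      ha <- histo_anova(aggregate_histology(h), outcomes = "elastin_pct",
                        posthoc = FALSE)
      ha$effects$p_value[ha$effects$term == "age_group"]
    }, numeric(1))
    rate <- mean(p_vals <= 0.05)
    ci_half <- 1.96 * sqrt(0.05 * 0.95 / 200)
    expect_gte(rate, 0.05 - ci_half)
    expect_lte(rate, 0.05 + ci_half)
  })
})

test_that("identical histology values are reported degenerate", {
  d <- tibble::tibble(
    horse_id = rep(sprintf("h%02d", 1:8), each = 2),
    age_group = rep(c("young", "old"), each = 8),
    location = rep(c("a", "b"), 8),
    imt_um = 1500
  )
  ha <- histo_anova(d, outcomes = "imt_um")
  expect_true(ha$degenerate$degenerate[1])
})
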