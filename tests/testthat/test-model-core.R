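test_that("parameter constructor enforces the valid domain", {
  expect_s3_class(arctan_params(100, -50, 20), "arctan_params")
  expect_error(arctan_params(0, 100, 50), "Am")
  expect_error(arctan_params(-5, 100, 50), "Am")
  expect_error(arctan_params(100, 100, 0), "P1")
  expect_error(arctan_params(100, Inf, 50), "P0")
  expect_error(area_at(arctan_params(100, 100, 50), "a"))
})

test_that("area curve matches the closed form and its limits", {
  # half the asymptote at the compliance peak
  expect_equal(area_at(arctan_params(100, 100, 50), 100), 50)
  # upper asymptote
  expect_lt(abs(area_at(arctan_params(100, 0, 1), 1e6) - 100), 1e-4)
  # frozen independent evaluation of the closed form at x = 20/58.6
  expect_equal(area_at(arctan_params(3313, 100, 58.6), 120),
               2003.3456164757, tolerance = 1e-10)
})

test_that("compliance is the Lorentzian with peak Am/(pi*P1) at P0", {
  p <- arctan_params(3313, 100, 58.6)
  expect_equal(compliance_at(p, 100), 17.9959155789573, tolerance = 1e-10)
  # even function of P - P0
  p2 <- arctan_params(100, 100, 50)
  expect_equal(compliance_at(p2, 130), compliance_at(p2, 70))
  # half-maximum at P0 +/- P1, for several random parameter draws
  withr::with_seed(11, {
    for (i in 1:10) {
      pr <- random_params()
      expect_equal(compliance_at(pr, pr$P0 + pr$P1),
                   compliance_at(pr, pr$P0) / 2)
    }
  })
})

test_that("distensibility is C/A, Am-free at the peak, with the expected argmax", {
  p <- arctan_params(100, 100, 58.6)
  expect_equal(distensibility_at(p, 100), 2 / (pi * 58.6))
  # D * A = C pointwise for random parameters and pressures
  withr::with_seed(12, {
    for (i in 1:10) {
      pr <- random_params()
      pp <- runif(5, 15, 300)
      expect_equal(distensibility_at(pr, pp) * area_at(pr, pp),
                   compliance_at(pr, pp))
    }
  })
  # frozen dense-grid oracle for the argmax on [15, 300]
  d <- max_distensibility(arctan_params(100, 100, 50), c(15, 300))
  expect_equal(d$pressure, 78.5511, tolerance = 1e-4)
  expect_equal(d$value, 0.0144922270755, tolerance = 1e-8)
})

test_that("area is strictly increasing and normalized at the tails", {
  withr::with_seed(13, {
    for (i in 1:20) {
      pr <- random_params()
      pp <- sort(runif(30, -200, 500))
      a <- area_at(pr, pp)
      expect_true(all(diff(a) > 0))
      expect_lt(abs(area_at(pr, -1e6)), 1e-3 * pr$Am)
      expect_lt(abs(area_at(pr, 1e6) - pr$Am), 1e-3 * pr$Am)
    }
  })
})

test_that("compliance equals the pressure derivative of area", {
  h <- 1e-3
  withr::with_seed(14, {
    for (i in 1:20) {
      pr <- random_params()
      pp <- runif(5, 15, 300)
      fd <- (area_at(pr, pp + h) - area_at(pr, pp - h)) / (2 * h)
      expect_equal(fd, compliance_at(pr, pp), tolerance = 1e-6)
    }
  })
})

test_that("noise-free fits recover the generating parameters exactly", {
  withr::with_seed(15, {
    for (i in 1:10) {
      truth <- random_params()
      fit <- fit_arctangent(noise_free_series(truth))
      expect_true(fit$converged)
      expect_equal(fit$params$Am, truth$Am, tolerance = 1e-6)
      expect_equal(fit$params$P0, truth$P0, tolerance = 1e-6)
      expect_equal(fit$params$P1, truth$P1, tolerance = 1e-6)
      expect_equal(fit$r_squared, 1, tolerance = 1e-9)
      expect_lt(fit$rss, 1e-8)
    }
  })
})

test_that("numeric argmax of compliance sits at the fitted P0", {
  withr::with_seed(16, {
    for (i in 1:5) {
      pr <- random_params()
      grid <- seq(15, 300, by = 0.1)
      p_hat <- grid[which.max(compliance_at(pr, grid))]
      expect_lt(abs(p_hat - min(max(pr$P0, 15), 300)), 0.1)
    }
  })
})

test_that("degenerate and undersized series are refused, not fitted", {
  # fewer than 5 distinct pressures -> classed error
  short <- new_pa_series("s", c(15, 30, 45, 60), rep(10, 4) + 1:4)
  expect_error(fit_arctangent(short), class = "vasofit_insufficient_data")
  # constant areas carry no signal: flagged, never spurious parameters
  flat <- new_pa_series("s", protocol_pressure_grid(), rep(50, 10))
  fit <- fit_arctangent(flat)
  expect_false(fit$converged)
  expect_identical(fit$status, "insufficient_signal")
  expect_null(fit$params)
})

test_that("2% multiplicative noise leaves Am recovery within 10%", {
  withr::with_seed(17, {
    truth <- arctan_params(1000, 110, 40)
    a <- area_at(truth, protocol_pressure_grid())
    obs <- a * (1 + rnorm(10, 0, 0.02))^2
    fit <- fit_arctangent(new_pa_series("s", protocol_pressure_grid(), obs))
    expect_true(fit$converged)
    expect_lt(abs(fit$params$Am - 1000) / 1000, 0.10)
  })
})

test_that("summary metrics report the curve maxima", {
  sm <- summary_metrics(arctan_params(3313, 100, 58.6))
  expect_equal(sm$max_area_mm2, 3313)
  expect_equal(sm$max_compliance_mm2_mmHg, 17.9959155789573, tolerance = 1e-9)
  expect_equal(sm$p_at_max_compliance_mmHg, 100)
  sm2 <- summary_metrics(arctan_params(100, 100, 50), c(15, 300))
  expect_equal(sm2$max_distensibility_per_mmHg, 0.0144922270755,
               tolerance = 1e-6)
  expect_equal(sm2$p_at_max_distensibility_mmHg, 78.5511, tolerance = 1e-3)
  # doubling P1 at fixed Am halves maximal compliance
  a <- summary_metrics(arctan_params(500, 100, 40))
  b <- summary_metrics(arctan_params(500, 100, 80))
  expect_equal(a$max_compliance_mm2_mmHg / 2, b$max_compliance_mm2_mmHg)
  # P0 outside the measured range: compliance maximum clipped to the edge
  sm3 <- summary_metrics(arctan_params(100, 350, 50), c(15, 300))
  expect_equal(sm3$p_at_max_compliance_mmHg, 300)
  expect_equal(sm3$max_compliance_mm2_mmHg,
               compliance_at(arctan_params(100, 350, 50), 300))
  expect_error(summary_metrics(arctan_params(100, 100, 50), c(300, 15)))
})
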