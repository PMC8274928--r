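# shared fixtures: all synthetic inputs are built in code

# noise-free pressure-area series from known parameters
noise_free_series <- function(params, grid = protocol_pressure_grid(),
                              sample_id = "s1") {
  new_pa_series(sample_id, grid, area_at(params, grid))
}

# long-format record table for one sample: triplicate diameters inverted
# from the model areas, optional multiplicative diameter noise
make_records <- function(params, sample_id = "s1", horse_id = "h01",
                         age_group = "young", location = "common_carotid",
                         grid = protocol_pressure_grid(), noise = 0,
                         replicates = 3) {
  a <- area_at(params, grid)
  d <- 2 * sqrt(a / pi)
  dm <- rep(d, each = replicates) *
    (1 + stats::rnorm(length(grid) * replicates, 0, noise))
  tibble::tibble(
    sample_id = sample_id, horse_id = horse_id, age_group = age_group,
    location = location,
    pressure_mmHg = rep(grid, each = replicates),
    replicate_index = rep(seq_len(replicates), length(grid)),
    diameter_mm = dm
  )
}

# random valid parameters in the regime the fit is designed for
random_params <- function() {
  arctan_params(Am = stats::runif(1, 50, 3500),
                P0 = stats::runif(1, 40, 200),
                P1 = stats::runif(1, 10, 150))
}

# n samples per group from shared or per-group parameters, as series list
make_group_series <- function(params_young, params_old, n_young, n_old,
                              noise = 0.02, grid = protocol_pressure_grid()) {
  mk <- function(params, i, ag) {
    a <- area_at(params, grid)
    d <- 2 * sqrt(a / pi)
    dbar <- vapply(d, function(di) {
      mean(di * (1 + stats::rnorm(3, 0, noise)))
    }, numeric(1))
    new_pa_series(paste0(ag, i), grid, pi * (dbar / 2)^2)
  }
  series <- c(lapply(seq_len(n_young), function(i) mk(params_young, i, "y")),
              lapply(seq_len(n_old), function(i) mk(params_old, i, "o")))
  list(series = series,
       groups = rep(c("young", "old"), c(n_young, n_old)))
}
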