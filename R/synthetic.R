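# Synthetic inflation-extension and histology datasets with known ground
# truth, emulating the study design they stand in for: 6 young / 14 old
# horses, a 10-point 15-300 mmHg pressure grid with triplicate ultrasound
# diameters, and five-frame histology slides with a layered tunica media.

# normal draws truncated to [lower, upper] by rejection, elementwise over
# vectors of means/SDs; degenerate sd -> clamped mean
rtrunc_norm <- function(mean, sd, lower = -Inf, upper = Inf) {
  n <- length(mean)
  sd <- rep_len(sd, n)
  out <- numeric(n)
  fixed <- sd <= 0
  out[fixed] <- pmin(pmax(mean[fixed], lower), upper)
  todo <- which(!fixed)
  for (i in 1:1000) {
    if (length(todo) == 0L) break
    out[todo] <- stats::rnorm(length(todo), mean[todo], sd[todo])
    todo <- todo[out[todo] < lower | out[todo] > upper]
  }
  if (length(todo) > 0L) out[todo] <- pmin(pmax(mean[todo], lower), upper)
  out
}

#' Default vessel profiles for the inflation generator
#'
#' One profile per mechanically tested location x age group, anchored to
#' the study-scale summary statistics: `Am` is the group mean maximal area
#' (mm^2) with its between-horse SD; `P0` defaults to 112.5 mmHg, the
#' midpoint of the 100-125 mmHg range where equine arteries reach maximal
#' compliance, with a 10 mmHg between-horse SD; `P1` is backed out of the
#' group mean maximal compliance as `Am / (pi * C_max)` with a 20% SD.
#' Diameter measurement noise defaults to 2% (multiplicative), a plausible
#' ultrasound caliper repeatability. The SDs and noise level are synthetic
#' modelling assumptions, not measured values.
#'
#' @return Tibble with columns `location`, `age_group`, `Am`, `sd_Am`,
#'   `P0`, `sd_P0`, `P1`, `sd_P1`, `diameter_noise`.
#' @examples
#' default_vessel_profiles()
#' @export
default_vessel_profiles <- function() {
  tab <- tibble::tribble(
    ~location,        ~age_group, ~Am,  ~sd_Am, ~c_max,
    "proximal_aorta", "young",    3313, 471,    18,
    "proximal_aorta", "old",      3154, 852,    17,
    "distal_aorta",   "young",    1039, 198,    10,
    "distal_aorta",   "old",      1132, 279,    10,
    "common_carotid", "young",    100,  14,     0.7,
    "common_carotid", "old",      114,  27,     0.8,
    "external_iliac", "young",    172,  64,     0.7,
    "external_iliac", "old",      215,  53,     0.8
  )
  tab |>
    dplyr::mutate(
      P0 = 112.5, sd_P0 = 10,
      P1 = .data$Am / (pi * .data$c_max),
      sd_P1 = 0.2 * .data$P1,
      diameter_noise = 0.02
    ) |>
    dplyr::select(-"c_max")
}

check_profiles <- function(profiles, cols) {
  stopifnot(is.data.frame(profiles))
  missing_cols <- setdiff(cols, names(profiles))
  if (length(missing_cols) > 0L) {
    stop("profiles are missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(profiles[, c("location", "age_group")])) {
    stop("duplicate location x age_group profile", call. = FALSE)
  }
  invisible(profiles)
}

#' Generate a synthetic inflation-extension dataset
#'
#' For every horse x location, true arctangent parameters are drawn around
#' the profile values (truncated to the valid domain), lumen areas are
#' evaluated on the pressure grid, inverted to inner diameters under the
#' circular-lumen assumption, and emitted as replicate diameter
#' measurements with multiplicative noise. The generating parameters are
#' returned alongside the records so recovery can be tested. Optionally a
#' fraction of old-group samples is rupture-truncated: their grid stops
#' below the rupture pressure, which is recorded as metadata.
#'
#' @param profiles Vessel profile tibble, see [default_vessel_profiles()].
#' @param n_young,n_old Horses per age group (study design: 6 and 14).
#' @param seed Integer seed; the generator is a pure function of
#'   (arguments, seed).
#' @param grid Pressure grid, mmHg.
#' @param replicates Diameter replicates per pressure (protocol: 3).
#' @param rupture Simulate rupture truncation?
#' @param rupture_fraction Fraction of old-group samples truncated (the
#'   study observed ruptures in a minority of arteries, mostly old horses).
#' @param rupture_pressure Pressure at which truncated samples fail, mmHg.
#' @return List with `records` (tibble: `sample_id`, `horse_id`,
#'   `age_group`, `location`, `pressure_mmHg`, `replicate_index`,
#'   `diameter_mm`, `rupture_pressure_mmHg`) and `truth` (tibble of the
#'   per-sample generating `Am`, `P0`, `P1` and noise level).
#' @examples
#' sim <- gen_inflation_dataset(n_young = 2, n_old = 3, seed = 7)
#' nrow(sim$records) # 5 horses x 4 locations x 10 pressures x 3 replicates
#' @export
gen_inflation_dataset <- function(profiles = default_vessel_profiles(),
                                  n_young = 6, n_old = 14, seed = 1,
                                  grid = protocol_pressure_grid(),
                                  replicates = 3,
                                  rupture = FALSE,
                                  rupture_fraction = 0.1,
                                  rupture_pressure = 250) {
  check_profiles(profiles, c("location", "age_group", "Am", "sd_Am", "P0",
                             "sd_P0", "P1", "sd_P1", "diameter_noise"))
  if (n_young < 1L || n_old < 1L) stop("need n >= 1 per group", call. = FALSE)
  if (any(profiles$Am <= 0) || any(profiles$P1 <= 0) ||
      any(profiles$sd_Am < 0) || any(profiles$sd_P1 < 0) ||
      any(profiles$diameter_noise < 0) || any(profiles$diameter_noise > 0.2)) {
    stop("invalid profile values", call. = FALSE)
  }
  stopifnot(is.numeric(grid), !is.unsorted(grid, strictly = TRUE),
            replicates >= 1L)
  horses <- tibble::tibble(
    horse_id = sprintf("h%02d", seq_len(n_young + n_old)),
    age_group = rep(c("young", "old"), c(n_young, n_old))
  )
  withr::with_seed(seed, {
    plan <- dplyr::inner_join(horses, profiles, by = "age_group",
                              relationship = "many-to-many")
    plan$sample_id <- paste(plan$horse_id, plan$location, sep = "_")
    n <- nrow(plan)
    plan$true_Am <- rtrunc_norm(plan$Am, plan$sd_Am, lower = 1e-6)
    plan$true_P0 <- stats::rnorm(n, plan$P0, plan$sd_P0)
    plan$true_P1 <- rtrunc_norm(plan$P1, plan$sd_P1, lower = 1e-6)
    plan$rupture_pressure_mmHg <- NA_real_
    if (isTRUE(rupture)) {
      old_idx <- which(plan$age_group == "old")
      hit <- old_idx[stats::runif(length(old_idx)) < rupture_fraction]
      plan$rupture_pressure_mmHg[hit] <- rupture_pressure
    }
    records <- purrr::map(seq_len(n), function(i) {
      g <- grid
      if (is.finite(plan$rupture_pressure_mmHg[i])) {
        g <- g[g < plan$rupture_pressure_mmHg[i]]
      }
      a <- area_at(arctan_params(plan$true_Am[i], plan$true_P0[i],
                                 plan$true_P1[i]), g)
      d <- 2 * sqrt(a / pi)
      m <- length(g) * replicates
      eps <- stats::rnorm(m, 0, plan$diameter_noise[i])
      tibble::tibble(
        sample_id = plan$sample_id[i],
        horse_id = plan$horse_id[i],
        age_group = plan$age_group[i],
        location = plan$location[i],
        pressure_mmHg = rep(g, each = replicates),
        replicate_index = rep(seq_len(replicates), length(g)),
        diameter_mm = pmax(rep(d, each = replicates) * (1 + eps), 1e-9),
        rupture_pressure_mmHg = plan$rupture_pressure_mmHg[i]
      )
    }) |> dplyr::bind_rows()
    truth <- tibble::as_tibble(plan[, c("sample_id", "horse_id", "age_group",
                                        "location", "true_Am", "true_P0",
                                        "true_P1", "diameter_noise",
                                        "rupture_pressure_mmHg")])
    list(records = records, truth = truth)
  })
}

#' Default histology profiles
#'
#' One profile per location x age group for the seven sampled locations,
#' anchored to study-scale means and between-horse SDs of intima-media
#' thickness and stain area percentages (elastin, smooth muscle actin,
#' collagen I and III). The proximal aorta has no thickness profile (not
#' assessed; wall too thick) and a single-layer media; the distal aorta
#' presents a two-layer media in 40% of horses; all other locations always
#' split into two layers. The layer-1 (smooth-muscle-rich) share of the
#' total thickness defaults to 0.6; frame-to-frame SD defaults to half the
#' between-horse SD. These structural parameters are synthetic modelling
#' assumptions.
#'
#' @return Tibble with columns `location`, `age_group`, `thickness_um`,
#'   `sd_thickness_um`, `<stain>_pct`, `sd_<stain>_pct` for the four
#'   stains, `two_layer_prob`, `layer1_frac`, `frame_sd_frac`.
#' @export
default_histo_profiles <- function() {
  tab <- tibble::tribble(
    ~location,                ~age_group, ~thickness_um, ~sd_thickness_um,
    ~elastin_pct, ~sd_elastin_pct, ~sma_pct, ~sd_sma_pct,
    ~col1_pct, ~sd_col1_pct, ~col3_pct, ~sd_col3_pct,
    "common_carotid",         "young", 1654, 145, 16, 7,  43, 6,  17, 5,  18, 2,
    "common_carotid",         "old",   1800, 225, 14, 5,  46, 6,  20, 5,  21, 6,
    "cranial_common_carotid", "young", 1622, 179, 15, 5,  43, 2,  20, 8,  19, 2,
    "cranial_common_carotid", "old",   1800, 231, 14, 5,  50, 6,  23, 10, 18, 5,
    "proximal_aorta",         "young", NA,   NA,  35, 11, 42, 7,  25, 11, 15, 5,
    "proximal_aorta",         "old",   NA,   NA,  34, 8,  45, 10, 23, 11, 18, 8,
    "distal_aorta",           "young", 2219, 361, 15, 4,  36, 6,  20, 9,  23, 8,
    "distal_aorta",           "old",   2300, 327, 14, 9,  41, 7,  16, 6,  21, 7,
    "median",                 "young", 1739, 302, 7,  2,  48, 9,  29, 10, 19, 4,
    "median",                 "old",   1885, 265, 9,  6,  51, 10, 20, 12, 16, 8,
    "external_iliac",         "young", 1655, 360, 11, 5,  41, 10, 27, 9,  23, 1,
    "external_iliac",         "old",   1840, 253, 11, 6,  44, 8,  20, 9,  22, 5,
    "femoral",                "young", 1469, 147, 12, 5,  39, 6,  21, 5,  25, 7,
    "femoral",                "old",   1870, 325, 15, 6,  41, 7,  15, 9,  24, 4
  )
  tab$two_layer_prob <- ifelse(tab$location == "proximal_aorta", 0,
                               ifelse(tab$location == "distal_aorta", 0.4, 1))
  tab$layer1_frac <- 0.6
  tab$frame_sd_frac <- 0.5
  tab
}

#' Generate a synthetic histology dataset
#'
#' For every horse x location, a horse-level mean is drawn per stain
#' (truncated normal on \[0, 100\]) and per thickness; the media is split
#' into two layers with probability `two_layer_prob` (layer 1 receiving
#' `layer1_frac` of the thickness); and five frame values per layer and
#' stain, plus five thickness measurements per layer, are drawn around the
#' horse-level means. Both layers share the horse's stain mean, so the
#' thickness-weighted overall area % recovers the profile mean in
#' expectation regardless of the split. Thickness is `NA` where the
#' profile has none (proximal aorta).
#'
#' @param profiles Histology profile tibble, see [default_histo_profiles()].
#' @inheritParams gen_inflation_dataset
#' @param n_frames Frames (and thickness measurements) per slide.
#' @return Tibble: `horse_id`, `age_group`, `location`, `layer`, `stain`,
#'   `frame_index`, `area_pct`, `thickness_um`.
#' @examples
#' h <- gen_histology_dataset(n_young = 2, n_old = 2, seed = 3)
#' dplyr::count(h, location, layer)
#' @export
gen_histology_dataset <- function(profiles = default_histo_profiles(),
                                  n_young = 6, n_old = 14, seed = 1,
                                  n_frames = 5) {
  check_profiles(profiles, c("location", "age_group", "thickness_um",
                             "sd_thickness_um",
                             paste0(histo_stains(), "_pct"),
                             paste0("sd_", histo_stains(), "_pct"),
                             "two_layer_prob", "layer1_frac",
                             "frame_sd_frac"))
  if (n_young < 1L || n_old < 1L) stop("need n >= 1 per group", call. = FALSE)
  pct_cols <- paste0(histo_stains(), "_pct")
  if (any(as.matrix(profiles[, pct_cols]) < 0, na.rm = TRUE) ||
      any(as.matrix(profiles[, pct_cols]) > 100, na.rm = TRUE)) {
    stop("profile area percentages must lie in [0, 100]", call. = FALSE)
  }
  horses <- tibble::tibble(
    horse_id = sprintf("h%02d", seq_len(n_young + n_old)),
    age_group = rep(c("young", "old"), c(n_young, n_old))
  )
  stains <- histo_stains()
  withr::with_seed(seed, {
    plan <- dplyr::inner_join(horses, profiles, by = "age_group",
                              relationship = "many-to-many")
    n <- nrow(plan)
    two_layer <- stats::runif(n) < plan$two_layer_prob
    have_t <- is.finite(plan$thickness_um)
    total_t <- rep(NA_real_, n)
    total_t[have_t] <- rtrunc_norm(plan$thickness_um[have_t],
                                   plan$sd_thickness_um[have_t], lower = 1)
    # horse-level stain means, shared by both layers of a slide
    mu <- vapply(stains, function(st) {
      rtrunc_norm(plan[[paste0(st, "_pct")]],
                  plan[[paste0("sd_", st, "_pct")]],
                  lower = 0, upper = 100)
    }, numeric(n))
    mu <- matrix(mu, nrow = n)
    frame_sd <- vapply(stains, function(st) {
      plan$frame_sd_frac * plan[[paste0("sd_", st, "_pct")]]
    }, numeric(n))
    frame_sd <- matrix(frame_sd, nrow = n)
    # one row per slide-layer
    sl_row <- rep(seq_len(n), ifelse(two_layer, 2L, 1L))
    sl_layer <- unlist(lapply(two_layer, function(b) if (b) 1:2 else 1L))
    frac <- ifelse(two_layer[sl_row],
                   ifelse(sl_layer == 1L, plan$layer1_frac[sl_row],
                          1 - plan$layer1_frac[sl_row]),
                   1)
    t_layer <- total_t[sl_row] * frac
    m <- length(sl_row)
    # per-layer thickness measurements (5% within-slide variability)
    t_rep <- rep(t_layer, each = n_frames)
    th_frames <- rep(NA_real_, m * n_frames)
    ok <- is.finite(t_rep)
    th_frames[ok] <- rtrunc_norm(t_rep[ok], 0.05 * t_rep[ok], lower = 1e-3)
    # long index: slide-layer (outer) x stain x frame (inner)
    sl_idx <- rep(seq_len(m), each = length(stains) * n_frames)
    st_idx <- rep(rep(seq_along(stains), each = n_frames), times = m)
    fr_idx <- rep(seq_len(n_frames), times = m * length(stains))
    row_idx <- sl_row[sl_idx]
    area <- rtrunc_norm(mu[cbind(row_idx, st_idx)],
                        frame_sd[cbind(row_idx, st_idx)],
                        lower = 0, upper = 100)
    tibble::tibble(
      horse_id = plan$horse_id[row_idx],
      age_group = plan$age_group[row_idx],
      location = plan$location[row_idx],
      layer = sl_layer[sl_idx],
      stain = stains[st_idx],
      frame_index = fr_idx,
      area_pct = area,
      thickness_um = th_frames[(sl_idx - 1L) * n_frames + fr_idx]
    )
  })
}
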