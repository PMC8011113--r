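#' Configuration for the synthetic canopy-reflectance generator
#'
#' The generator emulates a two-year winter-wheat irrigation trial:
#' 7 cultivars x 3 irrigation treatments (w0 = none, w1 = jointing,
#' w2 = jointing + grain filling) x 6 sampling dates x 2 seasons = 252
#' plot-level samples. Each sample gets a ground-truth LWC drawn around a
#' treatment-by-date mean profile (rise to a peak shortly after jointing
#' irrigation, then senescence-driven decline, with better-watered
#' treatments staying wetter late in the season) and a canopy reflectance
#' spectrum built from a phenomenological shape model: a low visible
#' baseline with a green peak, a logistic red-edge rise to a
#' biomass-scaled NIR plateau, a declining SWIR baseline, and Gaussian
#' water-absorption dips at 970, 1200, 1450 and 1940 nm whose depths grow
#' linearly with canopy water (LWC x biomass).
#'
#' @param seed integer seed governing all randomness.
#' @param n_cultivars number of cultivars (default 7).
#' @param treatments character vector of treatment labels (default
#'   `c("w0", "w1", "w2")`).
#' @param n_dates sampling dates per season (default 6).
#' @param n_years seasons (default 2).
#' @param lwc_profile_table numeric matrix `treatments x dates` of mean LWC
#'   (percent). The default peaks at date 2 and orders w2 > w1 > w0 from
#'   mid-season on, spanning roughly 56-88 percent.
#' @param cultivar_sd SD (percent) of the per-cultivar-by-year random
#'   intercept on LWC (default 1).
#' @param residual_sd SD (percent) of the per-sample LWC residual
#'   (default 1).
#' @param biomass_base baseline canopy biomass factor (default 1).
#' @param biomass_gain named per-treatment gain multiplied by date
#'   progression (0 at the first date, 1 at the last); default
#'   `c(w0 = 0.05, w1 = 0.15, w2 = 0.25)`, so NIR reflectance orders
#'   w2 > w1 > w0 late in the season by construction.
#' @param absorption_centers water-absorption band centres in nm.
#' @param absorption_widths Gaussian SD of each dip in nm.
#' @param absorption_strengths relative depth of each dip (the 1450 and
#'   1940 nm features are the strongest).
#' @param absorption_depth_coeff dip depth (reflectance fraction) per unit
#'   canopy water at relative strength 1 (default 0.20).
#' @param noise_sd additive spectral noise SD, reflectance fraction
#'   (default 0.005).
#' @param red_edge_center red-edge inflection wavelength in nm (default 720).
#' @param nir_plateau NIR plateau reflectance fraction at biomass 1
#'   (default 0.45).
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(seed = 20180101L,
                             n_cultivars = 7L,
                             treatments = c("w0", "w1", "w2"),
                             n_dates = 6L,
                             n_years = 2L,
                             lwc_profile_table = default_lwc_profile(treatments, n_dates),
                             cultivar_sd = 1.0,
                             residual_sd = 1.0,
                             biomass_base = 1.0,
                             biomass_gain = c(w0 = 0.05, w1 = 0.15, w2 = 0.25),
                             absorption_centers = c(970, 1200, 1450, 1940),
                             absorption_widths = c(35, 40, 60, 80),
                             absorption_strengths = c(0.35, 0.45, 1.0, 1.25),
                             absorption_depth_coeff = 0.20,
                             noise_sd = 0.005,
                             red_edge_center = 720,
                             nir_plateau = 0.45) {
  stopifnot(cultivar_sd >= 0, residual_sd >= 0, noise_sd >= 0,
            n_cultivars >= 1, n_dates >= 1, n_years >= 1,
            length(treatments) >= 1,
            length(absorption_centers) == length(absorption_widths),
            length(absorption_centers) == length(absorption_strengths))
  lwc_profile_table <- as.matrix(lwc_profile_table)
  if (nrow(lwc_profile_table) != length(treatments) ||
      ncol(lwc_profile_table) != n_dates) {
    stop("lwc_profile_table must be |treatments| x n_dates", call. = FALSE)
  }
  if (any(lwc_profile_table <= 0) || any(lwc_profile_table > 100)) {
    stop("lwc_profile_table values must be percent in (0, 100]",
         call. = FALSE)
  }
  rownames(lwc_profile_table) <- treatments
  if (is.null(names(biomass_gain))) names(biomass_gain) <- treatments
  structure(list(seed = as.integer(seed), n_cultivars = as.integer(n_cultivars),
                 treatments = treatments, n_dates = as.integer(n_dates),
                 n_years = as.integer(n_years),
                 lwc_profile_table = lwc_profile_table,
                 cultivar_sd = cultivar_sd, residual_sd = residual_sd,
                 biomass_base = biomass_base, biomass_gain = biomass_gain,
                 absorption_centers = absorption_centers,
                 absorption_widths = absorption_widths,
                 absorption_strengths = absorption_strengths,
                 absorption_depth_coeff = absorption_depth_coeff,
                 noise_sd = noise_sd, red_edge_center = red_edge_center,
                 nir_plateau = nir_plateau),
            class = "synthetic_config")
}

#' Default treatment-by-date LWC mean profile
#'
#' Unimodal in date (peak at the second sampling, ten days after jointing
#' irrigation) with treatments diverging as the season progresses:
#' w2 >= w1 >= w0 throughout and strictly so at the final date.
#'
#' @param treatments treatment labels.
#' @param n_dates number of sampling dates.
#' @return Numeric matrix `treatments x dates` of mean LWC percent.
#' @keywords internal
default_lwc_profile <- function(treatments = c("w0", "w1", "w2"),
                                n_dates = 6L) {
  full <- rbind(
    w0 = c(80, 86, 83, 76, 67, 57),
    w1 = c(81, 87, 84, 79, 73, 64),
    w2 = c(82, 88, 85, 81, 77, 70)
  )
  if (!all(treatments %in% rownames(full)) || n_dates > ncol(full)) {
    stop("default profile covers treatments w0..w2 and up to 6 dates; ",
         "supply lwc_profile_table explicitly", call. = FALSE)
  }
  full[treatments, seq_len(n_dates), drop = FALSE]
}

#' Mean LWC for one design cell
#'
#' @param treatment treatment label present in the config.
#' @param date_index sampling date, 1..`n_dates`.
#' @param config a [synthetic_config()].
#' @return Mean LWC percent for that treatment and date.
#' @export
lwc_profile <- function(treatment, date_index, config = synthetic_config()) {
  if (!treatment %in% config$treatments) {
    stop("unknown treatment: ", treatment, call. = FALSE)
  }
  if (!date_index %in% seq_len(config$n_dates)) {
    stop("date_index out of 1..", config$n_dates, call. = FALSE)
  }
  unname(config$lwc_profile_table[treatment, date_index])
}

#' Biomass factor for one design cell
#'
#' `biomass_base + biomass_gain[treatment] * (date_index - 1)/(n_dates - 1)`:
#' canopy biomass accumulates over the season, faster under more irrigation.
#'
#' @inheritParams lwc_profile
#' @return Unitless biomass factor.
#' @keywords internal
biomass_factor <- function(treatment, date_index, config) {
  prog <- if (config$n_dates > 1L) (date_index - 1) / (config$n_dates - 1) else 0
  config$biomass_base + unname(config$biomass_gain[treatment]) * prog
}

#' Noise-free spectral shape components
#'
#' @param config a [synthetic_config()].
#' @return A list of per-wavelength component vectors on the default grid.
#' @keywords internal
spectral_shape <- function(config) {
  wl <- default_grid()
  visible <- 0.045 + 0.065 * exp(-(wl - 550)^2 / (2 * 28^2)) -
    0.015 * exp(-(wl - 670)^2 / (2 * 30^2))
  red_edge <- 1 / (1 + exp(-(wl - config$red_edge_center) / 16))
  # SWIR baseline decays smoothly beyond the NIR plateau
  swir_decay <- 1 / (1 + exp((wl - 1420) / 260))
  plateau_shape <- red_edge * (0.35 + 0.65 * swir_decay)
  list(wl = wl, visible = visible, plateau_shape = plateau_shape)
}

#' Simulate a single canopy reflectance spectrum
#'
#' Deterministic given its arguments when `config$noise_sd == 0`; otherwise
#' additive Gaussian noise is drawn from the current RNG state.
#'
#' @param lwc true leaf water content, percent in (0, 100\].
#' @param biomass canopy biomass factor, > 0.
#' @param config a [synthetic_config()].
#' @return Reflectance vector on the default 2151-band grid, clipped to
#'   \[0, 1\].
#' @export
simulate_spectrum <- function(lwc, biomass, config = synthetic_config()) {
  stopifnot(lwc > 0, lwc <= 100, biomass > 0)
  sh <- spectral_shape(config)
  wl <- sh$wl
  base <- sh$visible + config$nir_plateau * biomass * sh$plateau_shape
  canopy_water <- (lwc / 100) * biomass
  dip <- numeric(length(wl))
  for (k in seq_along(config$absorption_centers)) {
    depth <- config$absorption_depth_coeff *
      config$absorption_strengths[k] * canopy_water
    dip <- dip + depth *
      exp(-(wl - config$absorption_centers[k])^2 /
            (2 * config$absorption_widths[k]^2))
  }
  # dips act on the vegetated (post-red-edge) part of the spectrum only
  refl <- base - dip * sh$plateau_shape
  if (config$noise_sd > 0) {
    refl <- refl + stats::rnorm(length(wl), 0, config$noise_sd)
  }
  clipped <- refl < 0 | refl > 1
  if (mean(clipped) > 0.5) {
    stop("configuration drives more than half of all bands out of [0, 1]",
         call. = FALSE)
  }
  pmin(pmax(refl, 0), 1)
}

#' Simulate the full two-year irrigation-trial dataset
#'
#' One sample per cultivar x treatment x date x year cell. Per-sample true
#' LWC = profile mean + a cultivar-by-year random intercept + residual
#' noise, truncated to (0, 100\]. The same seed always reproduces the same
#' dataset bit for bit.
#'
#' @param config a [synthetic_config()].
#' @return A list with `spectra` (a [spectra_set()] whose `meta$lwc` holds
#'   the true LWC) and `truth` (data frame: `sample_id`, `true_lwc`,
#'   `biomass`, `seed`).
#' @examples
#' sim <- simulate_dataset(synthetic_config(seed = 1))
#' n_samples(sim$spectra) # 252
#' @export
simulate_dataset <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  years <- paste0(2017 + seq_len(config$n_years), "-",
                  2018 + seq_len(config$n_years))
  design <- expand.grid(cultivar = seq_len(config$n_cultivars),
                        treatment = config$treatments,
                        date_index = seq_len(config$n_dates),
                        year = years,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  n <- nrow(design)
  # substream 1: cultivar-by-year random intercepts
  cult_eff <- matrix(stats::rnorm(config$n_cultivars * config$n_years,
                                  0, config$cultivar_sd),
                     nrow = config$n_cultivars,
                     dimnames = list(NULL, years))
  # substream 2: per-sample residuals
  resid <- stats::rnorm(n, 0, config$residual_sd)
  mu <- mapply(lwc_profile, design$treatment, design$date_index,
               MoreArgs = list(config = config))
  lwc <- mu + cult_eff[cbind(design$cultivar, match(design$year, years))] +
    resid
  lwc <- pmin(pmax(lwc, 1e-6), 100)
  biomass <- mapply(biomass_factor, design$treatment, design$date_index,
                    MoreArgs = list(config = config))
  # substream 3: spectra (noise drawn inside simulate_spectrum, row order)
  wl <- default_grid()
  refl <- matrix(NA_real_, n, length(wl))
  for (i in seq_len(n)) {
    refl[i, ] <- simulate_spectrum(lwc[i], biomass[i], config)
  }
  ids <- sprintf("y%d_c%d_%s_d%d",
                 match(design$year, years), design$cultivar,
                 design$treatment, design$date_index)
  meta <- data.frame(sample_id = ids, year = design$year,
                     cultivar = design$cultivar,
                     treatment = design$treatment,
                     date_index = design$date_index,
                     lwc = lwc, stringsAsFactors = FALSE)
  list(spectra = spectra_set(refl, wl, meta),
       truth = data.frame(sample_id = ids, true_lwc = lwc,
                          biomass = biomass, seed = config$seed,
                          stringsAsFactors = FALSE))
}
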