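#' Specify a Gaussian absorption band
#'
#' Bands are parameterized by center wavenumber, peak height and full width
#' at half maximum (FWHM), the natural reporting convention in vibrational
#' spectroscopy. The band profile is
#' \eqn{h \exp(-4 \ln 2 \, (\nu - c)^2 / w^2)} so that the absorbance at
#' \eqn{c \pm w/2} is exactly \eqn{h/2}, and the analytic area is
#' \eqn{h \, w \sqrt{\pi / (4 \ln 2)}}.
#'
#' @param center band center, cm^-1
#' @param height peak absorbance, AU (>= 0)
#' @param fwhm full width at half maximum, cm^-1 (> 0)
#' @return object of class `band_spec`
#' @export
band_spec <- function(center, height, fwhm) {
  if (!is.finite(center) || !is.finite(height) || !is.finite(fwhm))
    stop_cfg("band_spec: all parameters must be finite")
  if (height < 0) stop_cfg("band_spec: height must be >= 0 (got %g)", height)
  if (fwhm <= 0) stop_cfg("band_spec: fwhm must be > 0 (got %g)", fwhm)
  structure(list(center = center, height = height, fwhm = fwhm),
            class = "band_spec")
}

#' Analytic area of a Gaussian band
#' @param band a [band_spec()]
#' @return area in AU cm^-1
#' @export
band_area <- function(band) {
  band$height * band$fwhm * sqrt(pi / (4 * log(2)))
}

# evaluate one Gaussian band on a wavenumber grid
eval_band <- function(band, nu) {
  band$height * exp(-4 * log(2) * (nu - band$center)^2 / band$fwhm^2)
}

#' Simulation configuration for synthetic FTIR spectra
#'
#' Default range 900--4000 cm^-1 at 2 cm^-1 steps covers the band-region
#' conventions of both supported instruments; the step is configurable
#' because high-throughput transmission units commonly acquire at 6 cm^-1
#' resolution.
#'
#' @param seed integer; fully determines the generated noise
#' @param wavenumber_range `c(lo, hi)` in cm^-1, lo < hi
#' @param grid_step grid spacing, cm^-1 (> 0)
#' @param noise_sd additive Gaussian noise SD, AU (>= 0)
#' @param baseline_offset,baseline_slope affine baseline `offset + slope * nu`
#' @return object of class `sim_config`
#' @export
sim_config <- function(seed = 1L, wavenumber_range = c(900, 4000),
                       grid_step = 2, noise_sd = 0,
                       baseline_offset = 0, baseline_slope = 0) {
  if (length(wavenumber_range) != 2L ||
      !all(is.finite(wavenumber_range)) ||
      wavenumber_range[1L] >= wavenumber_range[2L])
    stop_cfg("sim_config: wavenumber_range must be c(lo, hi) with lo < hi")
  if (!is.finite(grid_step) || grid_step <= 0)
    stop_cfg("sim_config: grid_step must be > 0 (got %g)", grid_step)
  if (!is.finite(noise_sd) || noise_sd < 0)
    stop_cfg("sim_config: noise_sd must be >= 0 (got %g)", noise_sd)
  structure(list(seed = as.integer(seed),
                 wavenumber_range = as.numeric(wavenumber_range),
                 grid_step = grid_step, noise_sd = noise_sd,
                 baseline_offset = baseline_offset,
                 baseline_slope = baseline_slope),
            class = "sim_config")
}

#' Generate a synthetic FTIR spectrum
#'
#' Sum of Gaussian bands on an affine baseline with additive homoscedastic
#' Gaussian noise; a pure function of its arguments including the seed.
#'
#' @param bands list of [band_spec()] (may be empty for a pure baseline)
#' @param cfg a [sim_config()]
#' @param sample_id,instrument metadata carried on the returned spectrum
#' @return an [ftir_spectrum()]
#' @export
generate_spectrum <- function(bands = list(), cfg = sim_config(),
                              sample_id = "synthetic",
                              instrument = "other") {
  if (!inherits(cfg, "sim_config")) stop_cfg("cfg must be a sim_config")
  if (inherits(bands, "band_spec")) bands <- list(bands)
  nu <- seq(cfg$wavenumber_range[1L], cfg$wavenumber_range[2L],
            by = cfg$grid_step)
  for (b in bands) {
    if (!inherits(b, "band_spec")) stop_cfg("bands must be band_spec objects")
    if (b$center < nu[1L] || b$center > nu[length(nu)])
      stop_cfg("band center %g outside spectral range [%g, %g]",
               b$center, nu[1L], nu[length(nu)])
  }
  ab <- cfg$baseline_offset + cfg$baseline_slope * nu
  for (b in bands) ab <- ab + eval_band(b, nu)
  if (cfg$noise_sd > 0) {
    ab <- ab + withr::with_seed(cfg$seed, rnorm(length(nu), 0, cfg$noise_sd))
  }
  ftir_spectrum(nu, ab, instrument = instrument, sample_id = sample_id,
                metadata = list(generator = "gaussian_bands",
                                seed = cfg$seed))
}

#' Closed-form logistic growth trajectory
#'
#' \eqn{N(t) = K N_0 e^{r(t - \lambda)} / (K + N_0 (e^{r(t-\lambda)} - 1))}
#' for \eqn{t \ge \lambda}, and \eqn{N_0} during the lag phase.
#'
#' @param t time, hours
#' @param K carrying capacity (OD)
#' @param N0 initial density (OD), 0 < N0 < K
#' @param r intrinsic rate, per hour
#' @param lag_h lag duration, hours
#' @return OD values
#' @export
logistic_od <- function(t, K, N0, r, lag_h = 0) {
  td <- pmax(t - lag_h, 0)
  e <- exp(r * td)
  K * N0 * e / (K + N0 * (e - 1))
}

#' Closed-form integral of the (lag-free) logistic curve over [0, T]
#'
#' \eqn{\int_0^T N(t)\,dt = (K/r) \ln(1 + (N_0/K)(e^{rT} - 1))}; used as the
#' independent oracle for area-under-the-curve computations.
#'
#' @inheritParams logistic_od
#' @param T_end upper limit, hours
#' @return area in OD hours
#' @export
logistic_auc <- function(K, N0, r, T_end) {
  (K / r) * log(1 + (N0 / K) * (exp(r * T_end) - 1))
}

#' Generate a synthetic OD600 growth curve
#'
#' Logistic trajectory with an optional lag phase and additive Gaussian
#' noise, sampled on a uniform grid; deterministic per seed.
#'
#' @inheritParams logistic_od
#' @param t_end total incubation, hours
#' @param step sampling interval, hours (0.25 mirrors 15-minute reads)
#' @param noise_sd additive noise SD (OD)
#' @param seed integer seed
#' @param well,substrate,replicate metadata
#' @return a [growth_curve()]
#' @export
generate_growth_curve <- function(K = 1.5, N0 = 0.15, r = 0.25, lag_h = 0,
                                  t_end = 48, step = 0.25, noise_sd = 0,
                                  seed = 1L, well = "A1",
                                  substrate = "synthetic", replicate = 1L) {
  if (!is.finite(step) || step <= 0)
    stop_cfg("generate_growth_curve: step must be > 0 (got %g)", step)
  if (!(N0 > 0 && N0 < K))
    stop_cfg("generate_growth_curve: need 0 < N0 < K (N0=%g, K=%g)", N0, K)
  if (r <= 0) stop_cfg("generate_growth_curve: r must be > 0 (got %g)", r)
  t <- seq(0, t_end, by = step)
  od <- logistic_od(t, K, N0, r, lag_h)
  if (noise_sd > 0)
    od <- od + withr::with_seed(seed, rnorm(length(t), 0, noise_sd))
  growth_curve(t, od, well = well, substrate = substrate,
               replicate = replicate)
}

#' Generate a synthetic Biolog-style kinetic plate
#'
#' Each well is a logistic-like formazan accumulation of configurable
#' amplitude on top of a background trace shared by every well; the
#' designated no-carbon control carries the background only. Wells with
#' amplitude 0 are statistically identical to the control.
#'
#' @param per_well_params data frame with columns `well`, `amplitude`
#'   (AU above background), and optionally `rate` (per hour) and
#'   `midpoint` (hours); 96 unique wells required
#' @param control_well well id of the no-carbon control (amplitude ignored)
#' @param t_end,step time grid, hours
#' @param noise_sd additive noise SD (AU)
#' @param background_amplitude,background_rate,background_midpoint shared
#'   background kinetics (same logistic-like form)
#' @param seed integer seed
#' @param layout optional data frame `well`, `substrate`; defaults to the
#'   packaged PM1 map
#' @return a [kinetic_plate()]
#' @export
generate_biolog_plate <- function(per_well_params, control_well = "A1",
                                  t_end = 144, step = 6, noise_sd = 0,
                                  background_amplitude = 0.05,
                                  background_rate = 0.1,
                                  background_midpoint = 24,
                                  seed = 1L, layout = NULL) {
  p <- as.data.frame(per_well_params)
  if (anyDuplicated(p$well))
    stop_cfg("generate_biolog_plate: duplicate well ids: %s",
             paste(unique(p$well[duplicated(p$well)]), collapse = ", "))
  if (nrow(p) != 96L || !setequal(p$well, well_ids_96()))
    stop_cfg("generate_biolog_plate: per_well_params must cover all 96 wells")
  if (!control_well %in% p$well)
    stop_cfg("generate_biolog_plate: control well %s not found", control_well)
  if (is.null(p$rate)) p$rate <- 0.15
  if (is.null(p$midpoint)) p$midpoint <- t_end / 3
  p <- p[match(well_ids_96(), p$well), ]

  t <- seq(0, t_end, by = step)
  bg <- background_amplitude /
    (1 + exp(-background_rate * (t - background_midpoint)))
  vals <- withr::with_seed(seed, {
    m <- vapply(seq_len(96L), function(i) {
      amp <- if (p$well[i] == control_well) 0 else p$amplitude[i]
      y <- bg + amp / (1 + exp(-p$rate[i] * (t - p$midpoint[i])))
      if (noise_sd > 0) y <- y + rnorm(length(t), 0, noise_sd)
      y
    }, numeric(length(t)))
    colnames(m) <- p$well
    m
  })
  if (is.null(layout)) layout <- pm1_layout()
  kinetic_plate(t, vals, layout = layout, control_well = control_well)
}

#' Write a spectrum to the two-column CSV interchange format
#'
#' Header `wavenumber_cm-1,absorbance`; full double precision so that
#' write/read round-trips are bit-identical.
#'
#' @param s an [ftir_spectrum()]
#' @param path output file
#' @param descending write rows high-to-low wavenumber (many instrument
#'   exports are descending); the reader restores ascending order
#' @return `path`, invisibly
#' @export
write_spectrum_csv <- function(s, path, descending = FALSE) {
  stopifnot(inherits(s, "ftir_spectrum"))
  idx <- if (descending) rev(seq_along(s$wavenumber)) else
    seq_along(s$wavenumber)
  lines <- c("wavenumber_cm-1,absorbance",
             sprintf("%.17g,%.17g", s$wavenumber[idx], s$absorbance[idx]))
  writeLines(lines, path)
  invisible(path)
}

#' Write a kinetic plate to CSV (`time_h` column plus one column per well)
#' @param plate a [kinetic_plate()] or [growth_curve()] plate matrix
#' @param path output file
#' @return `path`, invisibly
#' @export
write_plate_csv <- function(plate, path) {
  stopifnot(inherits(plate, "kinetic_plate"))
  df <- data.frame(time_h = plate$times, plate$values, check.names = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
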