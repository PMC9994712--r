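#' Read a screening configuration from JSON
#'
#' The configuration is a nested key-value document: top-level `out_dir`
#' and `seed`, plus one section per stage under `stages` (any of `biolog`,
#' `growth`, `ftir`, `media`, `quant`). Only the stages present are run.
#'
#' @param path JSON file
#' @return config list (class `screening_config`)
#' @export
read_screening_config <- function(path) {
  if (!file.exists(path)) stop_cfg("no such config file: %s", path)
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  validate_screening_config(cfg)
}

#' @rdname read_screening_config
#' @param cfg a config list built in code
#' @export
validate_screening_config <- function(cfg) {
  if (is.null(cfg$out_dir)) stop_cfg("config: out_dir is required")
  if (is.null(cfg$seed)) cfg$seed <- 1L
  cfg$seed <- as.integer(cfg$seed)
  if (is.null(cfg$stages) || !length(cfg$stages))
    stop_cfg("config: at least one stage is required")
  unknown <- setdiff(names(cfg$stages),
                     c("biolog", "growth", "ftir", "media", "quant"))
  if (length(unknown))
    stop_cfg("config: unknown stage(s): %s", paste(unknown, collapse = ", "))
  structure(cfg, class = "screening_config")
}

log_line <- function(con, fmt, ...) {
  msg <- sprintf("[%s] %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                 sprintf(fmt, ...))
  writeLines(msg, con)
  message(msg)
}

#' Run the end-to-end screening workflow
#'
#' Executes the configured stages in the fixed order biolog, growth, ftir,
#' media, quant; writes tidy per-stage outputs under
#' `out_dir/<stage>/`, a combined `report.json`, and a timestamped
#' `log.txt` recording package version, seed and stage parameters. A stage
#' failure aborts with an error naming the stage; outputs of completed
#' stages are retained. Reruns with the same config and seed are
#' bit-identical for the deterministic stages.
#'
#' @param cfg a `screening_config` (from [read_screening_config()] or
#'   [validate_screening_config()])
#' @return the combined report, invisibly
#' @export
run_screening <- function(cfg) {
  cfg <- validate_screening_config(unclass(cfg))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(cfg$out_dir, "log.txt")
  con <- file(logf, open = "at")
  on.exit(close(con), add = TRUE)
  log_line(con, "phascreen %s | seed %d | stages: %s",
           as.character(packageVersion("phascreen")), cfg$seed,
           paste(names(cfg$stages), collapse = ", "))
  report <- list(package = "phascreen",
                 version = as.character(packageVersion("phascreen")),
                 seed = cfg$seed, stages = list())
  for (stage in intersect(c("biolog", "growth", "ftir", "media", "quant"),
                          names(cfg$stages))) {
    log_line(con, "stage %s: start", stage)
    sdir <- file.path(cfg$out_dir, stage)
    dir.create(sdir, showWarnings = FALSE)
    report$stages[[stage]] <- tryCatch(
      switch(stage,
             biolog = stage_biolog(cfg$stages$biolog, sdir),
             growth = stage_growth(cfg$stages$growth, sdir),
             ftir = stage_ftir(cfg$stages$ftir, sdir),
             media = stage_media(cfg$stages$media, sdir),
             quant = stage_quant(cfg$stages$quant, sdir)),
      error = function(e)
        stop_cfg("stage %s failed: %s", stage, conditionMessage(e)))
    log_line(con, "stage %s: done", stage)
  }
  jsonlite::write_json(report, file.path(cfg$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(report)
}

stage_biolog <- function(s, outdir) {
  cutoffs <- if (is.null(s$cutoffs)) c(0.15, 0.30, 1.00) else
    as.numeric(unlist(s$cutoffs))
  control <- if (is.null(s$control_well)) "A1" else s$control_well
  plates <- lapply(unlist(s$plates), read_kinetic_plate,
                   control_well = control)
  net <- average_plates(lapply(plates, subtract_background))
  calls <- classify_substrates(net, cutoffs = cutoffs)
  write.csv(calls, file.path(outdir, "phenotype_calls.csv"),
            row.names = FALSE)
  counts <- substrate_counts(calls)
  jsonlite::write_json(as.list(counts), file.path(outdir, "counts.json"),
                       auto_unbox = TRUE, digits = NA)
  export_heatmap(net, csv = file.path(outdir, "heatmap.csv"))
  list(n_plates = length(plates), counts = as.list(counts))
}

stage_growth <- function(s, outdir) {
  layout <- read.csv(unlist(s$layout), stringsAsFactors = FALSE)
  plate <- read_kinetic_plate(unlist(s$plate), layout = layout,
                              control_well = layout$well[1L])
  smoother <- if (is.null(s$smoother)) "spline" else s$smoother
  auc_scale <- if (is.null(s$auc_scale)) "linear" else s$auc_scale
  metrics <- lapply(colnames(plate$values), function(w) {
    row <- layout[layout$well == w, ]
    gc <- growth_curve(plate$times, plate$values[, w], well = w,
                       substrate = if (nrow(row)) row$substrate[1L] else w,
                       replicate = if (nrow(row) && "replicate" %in%
                                       names(row)) row$replicate[1L] else 1L)
    fit_growth_curve(gc, smoother = smoother, auc_scale = auc_scale)
  })
  df <- metrics_table(metrics)
  df$outlier_flag <- as.logical(detect_outliers(df))
  write.csv(df, file.path(outdir, "growth_metrics.csv"), row.names = FALSE)
  summ <- summarize_experiments(
    cbind(df, strain = "plate"), value_cols = c("gr", "auc"),
    group_cols = c("strain", "substrate"), level_cols = "replicate")
  write.csv(summ, file.path(outdir, "group_summary.csv"), row.names = FALSE)
  list(n_wells = nrow(df), n_outliers = sum(df$outlier_flag))
}

stage_ftir <- function(s, outdir) {
  profile <- instrument_profile(if (is.null(s$profile)) "cary" else
    s$profile)
  files <- if (!is.null(s$spectra_dir))
    list.files(unlist(s$spectra_dir), pattern = "\\.(csv|jdx|dx)$",
               full.names = TRUE)
  else unlist(s$spectra)
  if (!length(files)) stop_cfg("ftir stage: no spectra found")
  layout <- if (!is.null(s$layout))
    read.csv(unlist(s$layout), stringsAsFactors = FALSE) else NULL
  results <- lapply(files, function(f) {
    sp <- read_spectrum(f, instrument = profile$name)
    compute_ca1(sp, profile,
                smooth_window = if (is.null(s$smooth_window)) 9L else
                  as.integer(s$smooth_window),
                min_prominence = if (is.null(s$min_prominence)) 0.005 else
                  s$min_prominence,
                boundary = if (is.null(s$boundary)) 1733 else s$boundary)
  })
  df <- ca1_table(results)
  df$substrate <- if (!is.null(layout))
    layout$substrate[match(df$sample_id, layout$sample_id)] else
      df$sample_id
  write.csv(df, file.path(outdir, "ca1_results.csv"), row.names = FALSE)
  summ <- aggregate_ca1(df, df$substrate)
  write.csv(summ, file.path(outdir, "ca1_summary.csv"), row.names = FALSE)
  jsonlite::write_json(summ, file.path(outdir, "ca1_summary.json"),
                       digits = NA, na = "null")
  list(n_spectra = nrow(df),
       n_with_peak = sum(!is.na(df$carbonyl_peak_cm1)),
       classes = as.list(table(df$pha_class)))
}

stage_media <- function(s, outdir) {
  subs <- if (!is.null(s$substrates)) {
    df <- read.csv(unlist(s$substrates), stringsAsFactors = FALSE)
    lapply(seq_len(nrow(df)), function(i)
      substrate_spec(df$name[i], df$conc_g_per_L[i], df$molar_mass[i],
                     df$acetyl_coa_equiv[i],
                     if ("n_atoms" %in% names(df)) df$n_atoms[i] else 0))
  } else pha_substrates(as_specs = TRUE)
  medium <- switch(if (is.null(s$medium)) "mm_pha1" else s$medium,
                   mm_pha1 = mm_pha1(),
                   mm_pha2 = if (is.null(s$ye_n_fraction)) mm_pha2() else
                     mm_pha2(s$ye_n_fraction),
                   stop_cfg("media stage: unknown medium %s", s$medium))
  summ <- cn_summary(subs, medium)
  write.csv(summ$ratios, file.path(outdir, "cn_ratios.csv"),
            row.names = FALSE)
  jsonlite::write_json(summ[c("mean", "sd", "n")],
                       file.path(outdir, "cn_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  list(mean = summ$mean, sd = summ$sd, n = summ$n)
}

stage_quant <- function(s, outdir) {
  cal_df <- read.csv(unlist(s$calibration), stringsAsFactors = FALSE)
  cals <- lapply(split(cal_df, cal_df$monomer), function(d)
    fit_calibration(calibration_standard(d$monomer[1L], d$amount_mg,
                                         d$area)))
  samples <- read.csv(unlist(s$samples), stringsAsFactors = FALSE)
  rows <- lapply(split(samples, samples$sample_id), function(d) {
    res <- quantify_sample(setNames(d$area, d$monomer), cals,
                           pellet_mass_mg = d$pellet_mg[1L],
                           cdw_g_per_l = d$cdw_g_per_L[1L],
                           sample_id = d$sample_id[1L])
    out <- data.frame(sample_id = res$sample_id,
                      t(res$monomer_percent),
                      total_percent = res$total_percent,
                      cdw_g_per_l = res$cdw_g_per_l,
                      volumetric_g_per_l = res$volumetric_g_per_l,
                      check.names = FALSE)
    for (k in c("strain", "substrate", "experiment", "biological"))
      if (k %in% names(d)) out[[k]] <- d[[k]][1L]
    out
  })
  df <- do.call(rbind, rows)
  write.csv(df, file.path(outdir, "pha_quant.csv"), row.names = FALSE)
  res <- list(n_samples = nrow(df),
              mean_total_percent = mean(df$total_percent))
  if (all(c("strain", "substrate") %in% names(df))) {
    summ <- summarize_experiments(
      df, value_cols = c("total_percent", "cdw_g_per_l",
                         "volumetric_g_per_l"),
      group_cols = c("strain", "substrate"),
      level_cols = c("experiment", "biological"))
    write.csv(summ, file.path(outdir, "production_summary.csv"),
              row.names = FALSE)
  }
  res
}

#' Write a complete synthetic demo study
#'
#' Builds a self-contained fixture mimicking a two-strain screening
#' design, with a known truth manifest for recovery tests:
#' \itemize{
#'   \item a 15-substrate scl arm: every spectrum carries a carbonyl-ester
#'     band at 1728 cm^-1 with substrate-specific heights (so every
#'     spectrum classifies scl, and CA1 ranking follows the heights)
#'   \item a 14-substrate mcl arm: 10 substrates carry a band at
#'     1738 cm^-1, 4 carry none
#'   \item replicate Biolog PM1 plates for each arm whose per-well
#'     amplitudes are constructed to published-style count structure
#'     (49/44/25 and 54/51/20 metabolized at cutoffs 0.15/0.30/1.00)
#'   \item a growth plate (logistic curves, 15-minute sampling) + layout
#'   \item GC-FID calibration and sample tables
#' }
#' Different seeds change the noise, never the truth structure.
#'
#' @param seed integer seed
#' @param dir output directory (created)
#' @param noise_sd spectral noise SD, AU
#' @param n_replicates technical replicates per spectrum
#' @return `dir`, invisibly; truth written to `manifest.json`
#' @export
make_demo_fixture <- function(seed = 1L, dir = tempfile("phascreen_demo"),
                              noise_sd = 0.002, n_replicates = 3L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  subs <- pha_substrates()

  scl_heights <- c(
    "Na-gluconate" = 2.2, "Na-acetate" = 1.3, "L-Lactic acid" = 1.2,
    "D-Galactose" = 1.15, "L-Arabinose" = 1.05, "Glycerol" = 1.0,
    "Xylose" = 0.9, "Sucrose" = 0.8, "D-Mannitol" = 0.7, "Ethanol" = 0.6,
    "D-Fructose" = 0.5, "a-D-Glucose" = 0.45, "Mannose" = 0.4,
    "D-L-Malic acid" = 0.3, "N-acetylglucosamine" = 0.06)
  mcl_substrates <- setdiff(subs$name, "Ethanol")
  mcl_negative <- c("D-L-Malic acid", "Sucrose", "Na-acetate", "Mannose")
  mcl_heights <- setNames(rep(0.06, length(mcl_substrates)), mcl_substrates)
  mcl_heights[c("D-Fructose", "D-Mannitol")] <- 0.10
  mcl_heights[mcl_negative] <- 0

  write_arm <- function(arm, heights, center, sub_seed) {
    adir <- file.path(dir, "spectra", arm)
    dir.create(adir, recursive = TRUE, showWarnings = FALSE)
    layout <- list()
    k <- 0L
    for (nm in names(heights)) {
      for (rep in seq_len(n_replicates)) {
        k <- k + 1L
        bands <- list(band_spec(1650, 0.5, 40), band_spec(1545, 0.25, 35),
                      band_spec(2930, 0.15, 60))
        if (heights[[nm]] > 0)
          bands <- c(bands, list(band_spec(center, heights[[nm]], 20)))
        cfg <- sim_config(seed = sub_seed + k, noise_sd = noise_sd,
                          baseline_offset = 0.02, baseline_slope = 1e-5)
        sid <- sprintf("%s_%s_r%d", arm, gsub("[^A-Za-z0-9]+", "-", nm), rep)
        sp <- generate_spectrum(bands, cfg, sample_id = sid,
                                instrument = "hts_xt")
        write_spectrum_csv(sp, file.path(adir, paste0(sid, ".csv")))
        layout[[k]] <- data.frame(sample_id = sid, substrate = nm,
                                  replicate = rep)
      }
    }
    lay <- do.call(rbind, layout)
    write.csv(lay, file.path(dir, "spectra",
                             paste0(arm, "_layout.csv")), row.names = FALSE)
    lay
  }
  write_arm("scl_arm", scl_heights, 1728, seed * 1000L)
  write_arm("mcl_arm", mcl_heights, 1738, seed * 1000L + 500L)

  # Biolog plates: amplitude tiers force the per-cutoff counts
  biolog_amp <- function(n_low, n_mid, n_high) {
    wells <- well_ids_96()
    amp <- numeric(96L)
    idx <- which(wells != "A1")
    amp[idx[seq_len(n_high)]] <- 1.5
    amp[idx[n_high + seq_len(n_mid)]] <- 0.6
    amp[idx[n_high + n_mid + seq_len(n_low)]] <- 0.22
    data.frame(well = wells, amplitude = amp)
  }
  bdir <- file.path(dir, "biolog")
  dir.create(bdir, showWarnings = FALSE)
  arms <- list(scl_arm = c(low = 5L, mid = 19L, high = 25L),
               mcl_arm = c(low = 3L, mid = 31L, high = 20L))
  for (arm in names(arms)) {
    a <- arms[[arm]]
    pw <- biolog_amp(a[["low"]], a[["mid"]], a[["high"]])
    for (r in 1:3) {
      plate <- generate_biolog_plate(pw, control_well = "A1",
                                     noise_sd = 0.005,
                                     seed = seed * 100L +
                                       match(arm, names(arms)) * 10L + r)
      write_plate_csv(plate, file.path(bdir,
                                       sprintf("%s_plate%d.csv", arm, r)))
    }
  }

  # growth plate: 15 substrates x 3 replicates + 3 no-carbon controls
  gdir <- file.path(dir, "growth")
  dir.create(gdir, showWarnings = FALSE)
  gr_r <- setNames(seq(0.28, 0.10, length.out = nrow(subs)), subs$name)
  wells <- well_ids_96()[seq_len(nrow(subs) * 3L + 3L)]
  gl <- data.frame(well = wells,
                   substrate = c(rep("No carbon", 3L),
                                 rep(subs$name, each = 3L)),
                   replicate = c(1:3, rep(1:3, nrow(subs))))
  t <- seq(0, 96, by = 0.25)
  vals <- vapply(seq_len(nrow(gl)), function(i) {
    nm <- gl$substrate[i]
    if (nm == "No carbon") {
      withr::with_seed(seed * 7L + i, 0.12 + rnorm(length(t), 0, 0.003))
    } else {
      generate_growth_curve(K = 1.2, N0 = 0.12, r = gr_r[[nm]],
                            lag_h = 2, t_end = 96, step = 0.25,
                            noise_sd = 0.01, seed = seed * 7L + i)$od
    }
  }, numeric(length(t)))
  colnames(vals) <- gl$well
  write_plate_csv(kinetic_plate(t, vals, layout = gl,
                                control_well = gl$well[1L]),
                  file.path(gdir, "plate.csv"))
  write.csv(gl, file.path(gdir, "layout.csv"), row.names = FALSE)

  # GC-FID: linear detector response, areas back-generated from true
  # percentages so the quantification stage must invert the calibration
  qdir <- file.path(dir, "gcfid")
  dir.create(qdir, showWarnings = FALSE)
  slopes <- c(`3HB` = 1200, `3HHx` = 1100, `3HO` = 1000, `3HD` = 900)
  cal <- do.call(rbind, lapply(names(slopes), function(m)
    data.frame(monomer = m, amount_mg = c(0.5, 1, 2, 4),
               area = slopes[[m]] * c(0.5, 1, 2, 4))))
  write.csv(cal, file.path(qdir, "calibration.csv"), row.names = FALSE)
  truth_pct <- list(
    scl_glycerol = c(`3HB` = 17.0, `3HHx` = 0, `3HO` = 0, `3HD` = 0),
    mcl_glycerol = c(`3HB` = 1.42, `3HHx` = 2.84, `3HO` = 17.2,
                     `3HD` = 22.5))
  pellet_mg <- 20
  samp <- do.call(rbind, lapply(names(truth_pct), function(sid) {
    pct <- truth_pct[[sid]]
    data.frame(sample_id = sid, monomer = names(pct),
               area = pct / 100 * pellet_mg * slopes[names(pct)],
               pellet_mg = pellet_mg,
               cdw_g_per_L = if (startsWith(sid, "scl")) 3.9 else 1.2,
               strain = sub("_.*", "", sid),
               substrate = sub(".*_", "", sid),
               experiment = 1L, biological = 1L)
  }))
  write.csv(samp, file.path(qdir, "samples.csv"), row.names = FALSE)

  manifest <- list(
    seed = seed, noise_sd = noise_sd, n_replicates = n_replicates,
    scl_arm = list(center = 1728, heights = as.list(scl_heights)),
    mcl_arm = list(center = 1738, heights = as.list(mcl_heights),
                   negative_substrates = mcl_negative),
    biolog_counts = list(scl_arm = c(49L, 44L, 25L),
                         mcl_arm = c(54L, 51L, 20L)),
    growth_rates = as.list(gr_r),
    gcfid_truth_percent = lapply(truth_pct, as.list))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
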