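#' External-standard GC-FID calibration points
#'
#' @param monomer monomer label (3HB, 3HHx, 3HO, 3HD, or any user label)
#' @param amount_mg injected standard amounts, strictly increasing
#' @param peak_area detector responses, non-negative
#' @return object of class `calibration_standard`
#' @export
calibration_standard <- function(monomer, amount_mg, peak_area) {
  if (length(amount_mg) != length(peak_area) || length(amount_mg) < 2L)
    stop_cfg("calibration_standard %s: need >= 2 matched points", monomer)
  if (any(diff(amount_mg) <= 0))
    stop_cfg("calibration_standard %s: amounts must be strictly increasing",
             monomer)
  if (any(peak_area < 0))
    stop_cfg("calibration_standard %s: negative peak area", monomer)
  structure(list(monomer = monomer, amount_mg = as.numeric(amount_mg),
                 peak_area = as.numeric(peak_area)),
            class = "calibration_standard")
}

#' Fit a linear GC-FID calibration
#'
#' Least squares of `area ~ amount`, through the origin by default (the
#' FID response is linear through zero and single-level standards are
#' common). A non-positive slope indicates a failed calibration and
#' errors.
#'
#' @param std a [calibration_standard()]
#' @param through_origin force a zero intercept
#' @return list of class `calibration_fit`: `monomer`, `slope`
#'   (area per mg), `intercept`, `r_squared`
#' @export
fit_calibration <- function(std, through_origin = TRUE) {
  stopifnot(inherits(std, "calibration_standard"))
  d <- data.frame(amount = std$amount_mg, area = std$peak_area)
  fit <- if (through_origin) lm(area ~ amount + 0, data = d) else
    lm(area ~ amount, data = d)
  cf <- coef(fit)
  slope <- unname(cf[["amount"]])
  intercept <- if (through_origin) 0 else unname(cf[["(Intercept)"]])
  if (!is.finite(slope) || slope <= 0)
    stop_cfg("fit_calibration %s: non-positive slope %g", std$monomer, slope)
  structure(list(monomer = std$monomer, slope = slope,
                 intercept = intercept,
                 r_squared = suppressWarnings(summary(fit)$r.squared)),
            class = "calibration_fit")
}

#' Quantify PHA monomers in one sample from GC-FID peak areas
#'
#' Monomer mass is `(area - intercept) / slope`; each monomer is expressed
#' as weight percent of the freeze-dried pellet (cell dry weight), the
#' total is their sum, and the volumetric titre is
#' `total/100 * cdw_g_per_l`.
#'
#' @param areas named numeric vector of peak areas (names are monomers)
#' @param calibrations named list of `calibration_fit` (or a single fit)
#' @param pellet_mass_mg analysed pellet mass, mg (> 0)
#' @param cdw_g_per_l culture cell dry weight, g/L (optional; `NA` skips
#'   the volumetric figure)
#' @param sample_id label carried through
#' @return object of class `pha_quant_result`: `monomer_percent` (named),
#'   `total_percent`, `cdw_g_per_l`, `volumetric_g_per_l`
#' @export
quantify_sample <- function(areas, calibrations, pellet_mass_mg,
                            cdw_g_per_l = NA_real_, sample_id = "") {
  if (inherits(calibrations, "calibration_fit"))
    calibrations <- setNames(list(calibrations), calibrations$monomer)
  if (!is.finite(pellet_mass_mg) || pellet_mass_mg <= 0)
    stop_cfg("quantify_sample: pellet_mass_mg must be > 0")
  need <- names(areas)[areas > 0]
  missing_cal <- setdiff(need, names(calibrations))
  if (length(missing_cal))
    stop_cfg("quantify_sample [%s]: no calibration for monomer(s): %s",
             sample_id, paste(missing_cal, collapse = ", "))
  pct <- vapply(names(areas), function(m) {
    if (areas[[m]] <= 0) return(0)
    cal <- calibrations[[m]]
    mg <- (areas[[m]] - cal$intercept) / cal$slope
    max(0, mg) / pellet_mass_mg * 100
  }, 1.0)
  total <- sum(pct)
  if (total > 100)
    warning(sprintf("quantify_sample [%s]: total %.1f%% exceeds 100%%",
                    sample_id, total))
  structure(list(sample_id = sample_id, monomer_percent = pct,
                 total_percent = total, cdw_g_per_l = cdw_g_per_l,
                 volumetric_g_per_l = total / 100 * cdw_g_per_l),
            class = "pha_quant_result")
}

#' Summarize PHA quantification across a replicate hierarchy
#'
#' Averages bottom-up (technical within biological, biological within
#' experiment) and then reports mean and SD across experiments, matching
#' reporting conventions where the SD is taken between independent
#' experiments. With a balanced design the hierarchical mean equals the
#' flat mean. Any numeric column can be summarized.
#'
#' @param df data frame with grouping columns, hierarchy columns, and
#'   value columns
#' @param value_cols numeric columns to summarize
#' @param group_cols columns defining the reported groups
#' @param level_cols replicate hierarchy, outermost first; missing columns
#'   are skipped
#' @return data frame with one row per group and `<value>_mean`,
#'   `<value>_sd` columns (SD is `NA` for a single experiment)
#' @export
summarize_experiments <- function(df, value_cols,
                                  group_cols = c("strain", "substrate"),
                                  level_cols = c("experiment", "biological",
                                                 "technical")) {
  df <- as.data.frame(df)
  missing_g <- setdiff(group_cols, names(df))
  if (length(missing_g))
    stop_cfg("summarize_experiments: missing group column(s): %s",
             paste(missing_g, collapse = ", "))
  if (!nrow(df)) stop_cfg("summarize_experiments: empty input")
  levels_present <- intersect(level_cols, names(df))
  # collapse innermost levels one at a time
  while (length(levels_present) > 1L) {
    inner <- levels_present[length(levels_present)]
    keys <- c(group_cols, levels_present[-length(levels_present)])
    df <- aggregate(df[value_cols], df[keys], mean)
    levels_present <- levels_present[-length(levels_present)]
  }
  agg_mean <- aggregate(df[value_cols], df[group_cols], mean)
  agg_sd <- aggregate(df[value_cols], df[group_cols],
                      function(v) if (length(v) > 1L) sd(v) else NA_real_)
  names(agg_mean)[names(agg_mean) %in% value_cols] <-
    paste0(value_cols, "_mean")
  names(agg_sd)[names(agg_sd) %in% value_cols] <- paste0(value_cols, "_sd")
  merge(agg_mean, agg_sd, by = group_cols)
}
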