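#' Construct a growth curve
#'
#' One well's OD600 time series. Metric estimation requires at least 10
#' time points on a strictly increasing grid.
#'
#' @param times hours, strictly increasing
#' @param od OD600 values, same length, finite
#' @param well well id
#' @param substrate carbon substrate label
#' @param replicate replicate index
#' @return object of class `growth_curve`
#' @export
growth_curve <- function(times, od, well = "", substrate = "",
                         replicate = 1L) {
  times <- as.numeric(times); od <- as.numeric(od)
  if (length(times) != length(od))
    stop_cfg("growth_curve: times and od lengths differ")
  if (any(diff(times) <= 0))
    stop_cfg("growth_curve: times must be strictly increasing")
  if (!all(is.finite(od)))
    stop_cfg("growth_curve: non-finite OD values")
  structure(list(times = times, od = od, well = well,
                 substrate = substrate, replicate = as.integer(replicate)),
            class = "growth_curve")
}

#' Growth metrics from a single curve
#'
#' Fits a smoother to log OD and derives the four standard microplate
#' metrics:
#' \itemize{
#'   \item `gr`: maximum specific growth rate, the maximum of
#'     \eqn{d\,\ln \mathrm{OD}/dt} over the observation span (per hour)
#'   \item `t_gr`: time at which that maximum occurs (hours)
#'   \item `auc`: trapezoidal area under the raw (linear) OD curve
#'     (OD hours); set `auc_scale = "log"` for the log-OD variant
#'   \item `mse`: mean squared residual of the smoother on the log scale
#' }
#' OD is floored before the log transform so blank-subtracted noise near
#' zero cannot produce `-Inf`. Degenerate inputs (constant OD, smoother
#' failure) return `gr = 0` with `flagged = TRUE` rather than erroring, so
#' plate-scale runs survive empty wells.
#'
#' @param gc a [growth_curve()]
#' @param floor lower clamp applied to OD before `log` (OD units)
#' @param smoother `"spline"` (GCV smoothing spline, default)
#'   or `"gp"` (Gaussian-process-style smoother via `mgcv`, mirrors the
#'   AMiGA approach)
#' @param auc_scale `"linear"` or `"log"`
#' @param max_df cap on the spline's effective degrees of freedom; GCV can
#'   collapse to near-interpolation on noisy wells, and a growth curve
#'   never warrants more flexibility than this
#' @return object of class `growth_metrics`: list with `gr`, `t_gr`,
#'   `auc`, `mse`, `flagged`, plus the curve's `well`/`substrate` labels
#' @export
fit_growth_curve <- function(gc, floor = 0.01,
                             smoother = c("spline", "gp"),
                             auc_scale = c("linear", "log"),
                             max_df = 25) {
  stopifnot(inherits(gc, "growth_curve"))
  smoother <- match.arg(smoother)
  auc_scale <- match.arg(auc_scale)
  if (length(gc$times) < 10L)
    stop_cfg("fit_growth_curve [%s]: need >= 10 time points (got %d)",
             gc$well, length(gc$times))
  t <- gc$times
  y <- log(pmax(gc$od, floor))
  auc <- if (auc_scale == "linear") trapz(t, gc$od) else trapz(t, y)

  degenerate <- diff(range(y)) < 1e-9
  fit <- NULL
  if (!degenerate) {
    fit <- tryCatch({
      if (smoother == "spline") {
        # GCV with the standard anti-undersmoothing penalty (~1.4):
        # leave-one-out CV and plain GCV both undersmooth 15-min kinetic
        # reads enough to inflate the max derivative by 20-95%
        sp <- smooth.spline(t, y, cv = FALSE, penalty = 1.4)
        # GCV occasionally collapses to near-interpolation on noisy
        # wells (df ~ n), exploding the derivative; growth curves are
        # low-complexity, so cap the effective df
        if (sp$df > max_df) sp <- smooth.spline(t, y, df = max_df)
        grid <- seq(min(t), max(t), length.out = max(200L, 4L * length(t)))
        list(yhat = predict(sp, x = t)$y,
             dgrid = grid,
             dydt = predict(sp, x = grid, deriv = 1L)$y)
      } else {
        if (!requireNamespace("mgcv", quietly = TRUE))
          stop_cfg("smoother = 'gp' requires the mgcv package")
        k <- min(30L, length(t) - 1L)
        gm <- mgcv::gam(y ~ s(t, bs = "gp", k = k),
                        data = data.frame(t = t, y = y), method = "REML")
        grid <- seq(min(t), max(t), length.out = max(200L, 4L * length(t)))
        yg <- predict(gm, newdata = data.frame(t = grid))
        list(yhat = as.numeric(predict(gm, newdata = data.frame(t = t))),
             dgrid = grid[-1L],
             dydt = diff(yg) / diff(grid))
      }
    }, error = function(e) NULL)
  }

  if (is.null(fit)) {
    m <- list(gr = 0, t_gr = t[1L], auc = auc,
              mse = if (degenerate) 0 else NA_real_, flagged = TRUE)
  } else {
    i <- which.max(fit$dydt)
    m <- list(gr = max(0, fit$dydt[i]), t_gr = fit$dgrid[i], auc = auc,
              mse = mean((y - fit$yhat)^2), flagged = FALSE)
  }
  structure(c(m, list(well = gc$well, substrate = gc$substrate,
                      replicate = gc$replicate, smoother = smoother)),
            class = "growth_metrics")
}

#' @export
print.growth_metrics <- function(x, ...) {
  cat(sprintf("<growth_metrics> %s (%s): gr = %.4g /h at t = %.3g h, AUC = %.4g, MSE = %.3g%s\n",
              x$well, x$substrate, x$gr, x$t_gr, x$auc, x$mse,
              if (isTRUE(x$flagged)) " [flagged]" else ""))
  invisible(x)
}

#' Collect growth metrics into a tidy data frame
#' @param metrics list of `growth_metrics`
#' @return data frame, one row per curve
#' @export
metrics_table <- function(metrics) {
  if (inherits(metrics, "growth_metrics")) metrics <- list(metrics)
  do.call(rbind, lapply(metrics, function(m)
    data.frame(well = m$well, substrate = m$substrate,
               replicate = m$replicate, gr = m$gr, t_gr = m$t_gr,
               auc = m$auc, mse = m$mse, flagged = m$flagged)))
}

#' Flag outlier curves by box-plot fences on the fitted metrics
#'
#' For each metric, quartiles are computed by linear interpolation and a
#' curve is flagged when the value falls strictly outside
#' `[Q1 - 1.5 IQR, Q3 + 1.5 IQR]` for any of the requested fields. With
#' fewer than 4 curves the fences are meaningless; a warning is issued and
#' nothing is flagged.
#'
#' @param metrics list of `growth_metrics` or a [metrics_table()] data frame
#' @param fields metric columns to screen
#' @return logical vector (one flag per curve) with a `per_field` logical
#'   matrix attribute
#' @export
detect_outliers <- function(metrics, fields = c("gr", "t_gr", "mse", "auc")) {
  df <- if (is.data.frame(metrics)) metrics else metrics_table(metrics)
  missing_f <- setdiff(fields, names(df))
  if (length(missing_f))
    stop_cfg("detect_outliers: unknown fields: %s",
             paste(missing_f, collapse = ", "))
  n <- nrow(df)
  per <- matrix(FALSE, n, length(fields), dimnames = list(NULL, fields))
  if (n < 4L) {
    warning("detect_outliers: fewer than 4 curves; no flags assigned")
    flags <- rep(FALSE, n)
    attr(flags, "per_field") <- per
    return(flags)
  }
  for (f in fields) {
    v <- df[[f]]
    ok <- is.finite(v)
    q <- quantile(v[ok], c(0.25, 0.75), type = 7, names = FALSE)
    iqr <- q[2L] - q[1L]
    per[ok, f] <- v[ok] < q[1L] - 1.5 * iqr | v[ok] > q[2L] + 1.5 * iqr
  }
  flags <- rowSums(per) > 0
  attr(flags, "per_field") <- per
  flags
}

#' Compare a substrate group to a control group on one metric
#'
#' Reports group and control mean and SD, the band rule used in microplate
#' screening figures (group mean outside control mean +/- 2 control SD;
#' the boundary itself counts as inside), and a two-sided Welch t-test.
#' Controls of size one cannot define a band or a t-test; both are `NA`.
#'
#' @param group,control lists of `growth_metrics` or metric data frames
#' @param metric_field which metric to compare (e.g. `"gr"`, `"auc"`)
#' @return list with `metric`, `group_mean`, `group_sd`, `control_mean`,
#'   `control_sd`, `outside_band`, `p_value`, `n_group`, `n_control`
#' @export
compare_to_control <- function(group, control, metric_field = "gr") {
  gv <- (if (is.data.frame(group)) group else
    metrics_table(group))[[metric_field]]
  cv <- (if (is.data.frame(control)) control else
    metrics_table(control))[[metric_field]]
  if (!length(gv) || !length(cv))
    stop_cfg("compare_to_control: both groups must be non-empty")
  res <- list(metric = metric_field,
              group_mean = mean(gv),
              group_sd = if (length(gv) > 1L) sd(gv) else NA_real_,
              control_mean = mean(cv),
              control_sd = if (length(cv) > 1L) sd(cv) else NA_real_,
              n_group = length(gv), n_control = length(cv))
  if (length(cv) < 2L) {
    res$outside_band <- NA
    res$p_value <- NA_real_
  } else {
    # boundary counts as inside; guard against floating-point ties
    delta <- abs(res$group_mean - res$control_mean)
    band <- 2 * res$control_sd
    res$outside_band <- delta > band * (1 + 1e-10)
    res$p_value <- if (length(gv) > 1L &&
                       (sd(gv) > 0 || sd(cv) > 0))
      t.test(gv, cv)$p.value else NA_real_
  }
  res
}

#' Read a kinetic plate CSV (`time_h` plus one column per well)
#'
#' @param path plate CSV
#' @param layout optional data frame `well`, `substrate` (and optionally
#'   `role`, `replicate`); defaults to the packaged PM1 map when the file
#'   carries all 96 wells
#' @param control_well no-carbon control well id
#' @return a [kinetic_plate()]
#' @export
read_kinetic_plate <- function(path, layout = NULL, control_well = "A1") {
  if (!file.exists(path)) stop_cfg("read_kinetic_plate: no such file: %s", path)
  df <- read.csv(path, check.names = FALSE)
  if (!"time_h" %in% names(df))
    stop_cfg("%s: missing time_h column", path)
  wells <- setdiff(names(df), "time_h")
  vals <- as.matrix(df[wells])
  if (is.null(layout)) {
    layout <- if (setequal(wells, well_ids_96())) pm1_layout() else
      data.frame(well = wells, substrate = wells)
  }
  kinetic_plate(df$time_h, vals, layout = layout,
                control_well = control_well)
}
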