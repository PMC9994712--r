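#' Construct an FTIR spectrum
#'
#' The canonical container for one whole-cell infrared measurement: a
#' strictly increasing wavenumber grid with matched absorbances. Instrument
#' exports stored high-to-low are reversed at the I/O boundary, so the
#' in-memory grid is always ascending.
#'
#' @param wavenumber numeric, cm^-1, strictly increasing after sorting
#' @param absorbance numeric, AU, same length (>= 8 points)
#' @param instrument one of `"cary"`, `"hts_xt"`, `"other"`
#' @param sample_id sample identifier
#' @param metadata named list of free-form metadata
#' @return object of class `ftir_spectrum`
#' @export
ftir_spectrum <- function(wavenumber, absorbance,
                          instrument = c("other", "cary", "hts_xt"),
                          sample_id = "", metadata = list()) {
  instrument <- match.arg(instrument)
  wavenumber <- as.numeric(wavenumber)
  absorbance <- as.numeric(absorbance)
  if (length(wavenumber) != length(absorbance))
    stop_cfg("ftir_spectrum: wavenumber and absorbance lengths differ (%d vs %d)",
             length(wavenumber), length(absorbance))
  if (length(wavenumber) < 8L)
    stop_cfg("ftir_spectrum: need >= 8 points (got %d)", length(wavenumber))
  if (!all(is.finite(wavenumber)) || !all(is.finite(absorbance)))
    stop_cfg("ftir_spectrum: non-finite values")
  d <- diff(wavenumber)
  if (any(d < 0)) {
    # accept a descending grid and flip it
    if (all(d < 0)) {
      wavenumber <- rev(wavenumber)
      absorbance <- rev(absorbance)
      d <- diff(wavenumber)
    } else {
      stop_cfg("ftir_spectrum: wavenumber grid is not monotone")
    }
  }
  if (any(d == 0))
    stop_cfg("ftir_spectrum: duplicated wavenumber %g",
             wavenumber[which(d == 0)[1L]])
  structure(list(wavenumber = wavenumber, absorbance = absorbance,
                 instrument = instrument, sample_id = sample_id,
                 metadata = metadata),
            class = "ftir_spectrum")
}

#' @export
print.ftir_spectrum <- function(x, ...) {
  cat(sprintf("<ftir_spectrum> %s [%s]: %d points, %g-%g cm-1\n",
              x$sample_id, x$instrument, length(x$wavenumber),
              min(x$wavenumber), max(x$wavenumber)))
  invisible(x)
}

#' Define an integration band region
#' @param name region label, e.g. `"carbonyl_ester"` or `"amide_I"`
#' @param lo,hi region bounds, cm^-1, lo < hi
#' @return object of class `band_region`
#' @export
band_region <- function(name, lo, hi) {
  if (!is.finite(lo) || !is.finite(hi) || lo >= hi)
    stop_cfg("band_region %s: need lo < hi (got %g, %g)", name, lo, hi)
  structure(list(name = name, lo = lo, hi = hi), class = "band_region")
}

#' Instrument band-region and normalization conventions
#'
#' The two supported systems differ in their published carbonyl-ester and
#' amide I integration windows:
#' \itemize{
#'   \item ATR (`"cary"`): carbonyl 1763--1705, amide I 1705--1580 cm^-1
#'   \item high-throughput transmission (`"hts_xt"`): carbonyl 1772--1710,
#'     amide I 1710--1600 cm^-1
#' }
#' Both normalize whole-cell spectra to 0.5 AU at the amide I anchor,
#' 1650 cm^-1, which serves as an internal protein standard.
#'
#' @param name `"cary"` or `"hts_xt"`, or `"custom"` with explicit regions
#' @param carbonyl_region,amide1_region [band_region()] overrides
#' @param norm_anchor anchor wavenumber, cm^-1
#' @param norm_target anchor absorbance after normalization, AU
#' @return object of class `instrument_profile`
#' @export
instrument_profile <- function(name = c("cary", "hts_xt", "custom"),
                               carbonyl_region = NULL, amide1_region = NULL,
                               norm_anchor = 1650, norm_target = 0.5) {
  name <- match.arg(name)
  if (name == "cary") {
    if (is.null(carbonyl_region))
      carbonyl_region <- band_region("carbonyl_ester", 1705, 1763)
    if (is.null(amide1_region))
      amide1_region <- band_region("amide_I", 1580, 1705)
  } else if (name == "hts_xt") {
    if (is.null(carbonyl_region))
      carbonyl_region <- band_region("carbonyl_ester", 1710, 1772)
    if (is.null(amide1_region))
      amide1_region <- band_region("amide_I", 1600, 1710)
  } else if (is.null(carbonyl_region) || is.null(amide1_region)) {
    stop_cfg("custom instrument_profile requires explicit band regions")
  }
  if (carbonyl_region$lo < amide1_region$hi &&
      amide1_region$lo < carbonyl_region$hi)
    stop_cfg("instrument_profile: band regions overlap")
  if (norm_anchor < amide1_region$lo || norm_anchor > amide1_region$hi)
    stop_cfg("instrument_profile: anchor %g outside amide I region",
             norm_anchor)
  structure(list(name = name, carbonyl_region = carbonyl_region,
                 amide1_region = amide1_region, norm_anchor = norm_anchor,
                 norm_target = norm_target),
            class = "instrument_profile")
}

# linear interpolation of absorbance at arbitrary wavenumbers
interp_abs <- function(s, nu) {
  if (any(nu < s$wavenumber[1L]) || any(nu > s$wavenumber[length(s$wavenumber)]))
    stop_cfg("wavenumber %g outside grid span [%g, %g]",
             nu[which(nu < s$wavenumber[1L] | nu > max(s$wavenumber))[1L]],
             s$wavenumber[1L], max(s$wavenumber))
  approx(s$wavenumber, s$absorbance, xout = nu, ties = "ordered")$y
}

#' Read a spectrum from CSV or JCAMP-DX
#'
#' CSV must carry two numeric columns (wavenumber, absorbance); descending
#' files are reversed so the returned grid is ascending. JCAMP-DX support
#' covers AFFN-encoded `##XYPOINTS=(XY..XY)` and `##XYDATA=(X++(Y..Y))`
#' tables with optional X/Y factors.
#'
#' @param path input file
#' @param format `"csv"` or `"jcamp"`; default guesses from the extension
#' @param instrument,sample_id metadata for the returned spectrum (sample_id
#'   defaults to the file stem)
#' @return an [ftir_spectrum()]
#' @export
read_spectrum <- function(path, format = c("auto", "csv", "jcamp"),
                          instrument = "other", sample_id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_cfg("read_spectrum: no such file: %s", path)
  if (format == "auto") {
    format <- if (grepl("\\.(jdx|dx|jcm)$", tolower(path))) "jcamp" else "csv"
  }
  if (is.null(sample_id))
    sample_id <- sub("\\.[^.]*$", "", basename(path))
  if (format == "csv") {
    xy <- read_spectrum_csv(path)
  } else {
    xy <- read_spectrum_jcamp(path)
  }
  if (nrow(xy) >= 2L) {
    dups <- duplicated(xy$x)
    if (any(dups))
      stop_cfg("%s: duplicated wavenumber %g at line %d",
               path, xy$x[which(dups)[1L]], xy$line[which(dups)[1L]])
    if (!(all(diff(xy$x) > 0) || all(diff(xy$x) < 0))) {
      bad <- which(sign(diff(xy$x)) != sign(xy$x[2L] - xy$x[1L]))[1L] + 1L
      stop_cfg("%s: non-monotone wavenumber grid at line %d", path,
               xy$line[bad])
    }
  }
  ftir_spectrum(xy$x, xy$y, instrument = instrument, sample_id = sample_id)
}

read_spectrum_csv <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L) stop_cfg("%s: empty spectral file", path)
  start <- 1L
  first <- strsplit(lines[1L], ",", fixed = TRUE)[[1L]]
  if (suppressWarnings(anyNA(as.numeric(first[1:2])))) start <- 2L
  body <- lines[start:length(lines)]
  parts <- strsplit(body, ",", fixed = TRUE)
  bad <- which(vapply(parts, length, 1L) < 2L)
  if (length(bad))
    stop_cfg("%s: malformed row at line %d: %s", path, bad[1L] + start - 1L,
             body[bad[1L]])
  x <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 1L)))
  y <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 2L)))
  nn <- which(is.na(x) | is.na(y))
  if (length(nn))
    stop_cfg("%s: non-numeric value at line %d: %s", path,
             nn[1L] + start - 1L, body[nn[1L]])
  data.frame(x = x, y = y, line = seq_along(x) + start - 1L)
}

read_spectrum_jcamp <- function(path) {
  lines <- readLines(path, warn = FALSE)
  getldr <- function(key) {
    hit <- grep(paste0("^##", key, "="), lines, ignore.case = TRUE,
                value = TRUE)
    if (!length(hit)) return(NA_real_)
    suppressWarnings(as.numeric(sub("^##[^=]*=", "", hit[1L])))
  }
  xf <- getldr("XFACTOR"); if (is.na(xf)) xf <- 1
  yf <- getldr("YFACTOR"); if (is.na(yf)) yf <- 1
  start <- grep("^##(XYDATA|XYPOINTS)\\s*=", lines, ignore.case = TRUE)
  if (!length(start)) stop_cfg("%s: no XYDATA/XYPOINTS block", path)
  header <- lines[start[1L]]
  stop_at <- grep("^##", lines)
  stop_at <- stop_at[stop_at > start[1L]]
  end <- if (length(stop_at)) stop_at[1L] - 1L else length(lines)
  body <- lines[(start[1L] + 1L):end]
  body <- body[nzchar(trimws(body))]
  if (grepl("XYPOINTS|\\(XY\\.\\.XY\\)", header, ignore.case = TRUE)) {
    toks <- unlist(strsplit(trimws(body), "[,;[:space:]]+"))
    vals <- suppressWarnings(as.numeric(toks[nzchar(toks)]))
    if (anyNA(vals) || length(vals) %% 2L != 0L)
      stop_cfg("%s: unparseable XYPOINTS data", path)
    x <- vals[seq(1L, length(vals), 2L)] * xf
    y <- vals[seq(2L, length(vals), 2L)] * yf
  } else {
    # X++(Y..Y): each row begins with an X value followed by Y values
    x <- numeric(0); y <- numeric(0)
    for (i in seq_along(body)) {
      toks <- unlist(strsplit(trimws(body[i]), "[[:space:]]+"))
      vals <- suppressWarnings(as.numeric(toks[nzchar(toks)]))
      if (anyNA(vals) || length(vals) < 2L)
        stop_cfg("%s: unparseable XYDATA row at line %d", path,
                 start[1L] + i)
      x0 <- vals[1L]; ys <- vals[-1L]
      # per-row X spacing from DELTAX or inferred on the next row
      dx <- getldr("DELTAX")
      if (is.na(dx)) {
        nx <- getldr("NPOINTS")
        fx <- getldr("FIRSTX"); lx <- getldr("LASTX")
        dx <- if (!anyNA(c(nx, fx, lx)) && nx > 1) (lx - fx) / (nx - 1) else 1
      }
      x <- c(x, x0 + dx * (seq_along(ys) - 1L))
      y <- c(y, ys)
    }
    x <- x * xf; y <- y * yf
  }
  data.frame(x = x, y = y, line = seq_along(x))
}

#' Normalize a spectrum to a fixed absorbance at the amide I anchor
#'
#' Scales every absorbance by `norm_target / A(anchor)` where `A(anchor)`
#' is obtained by linear interpolation between bracketing grid points (real
#' grids rarely contain 1650.0 exactly). Makes downstream band areas and
#' CA1 ratios invariant to the amount of biomass deposited on the sensor.
#' Idempotent to machine precision.
#'
#' @param s an [ftir_spectrum()]
#' @param profile an [instrument_profile()]
#' @return normalized [ftir_spectrum()]
#' @export
normalize_spectrum <- function(s, profile = instrument_profile("cary")) {
  stopifnot(inherits(s, "ftir_spectrum"),
            inherits(profile, "instrument_profile"))
  a <- interp_abs(s, profile$norm_anchor)
  if (!is.finite(a) || a <= 0)
    stop_cfg("normalize_spectrum: anchor absorbance A(%g) = %g is not > 0; %s",
             profile$norm_anchor, a, "blank or degenerate sample")
  s$absorbance <- s$absorbance * (profile$norm_target / a)
  s$metadata$normalized <- TRUE
  s
}

#' Subtract the straight line through the spectrum's first and last points
#'
#' The whole-spectrum "linear" baseline correction: endpoints become
#' exactly zero. Mathematically inert for chord-subtracted band areas, but
#' kept in the processing chain so reported peak heights match the
#' conventional workflow.
#'
#' @param s an [ftir_spectrum()]
#' @return baseline-corrected [ftir_spectrum()]
#' @export
baseline_correct_linear <- function(s) {
  stopifnot(inherits(s, "ftir_spectrum"))
  n <- length(s$wavenumber)
  x1 <- s$wavenumber[1L]; x2 <- s$wavenumber[n]
  y1 <- s$absorbance[1L]; y2 <- s$absorbance[n]
  slope <- (y2 - y1) / (x2 - x1)
  s$absorbance <- s$absorbance - (y1 + slope * (s$wavenumber - x1))
  s$metadata$baseline <- "linear_endpoints"
  s
}

#' Integrate a band above its individual (chord) baseline
#'
#' Implements the per-region "individual baseline" integral: a chord is
#' drawn from `(lo, A(lo))` to `(hi, A(hi))` with interpolated endpoint
#' values, and the trapezoidal integral of `A - chord` is taken over
#' `[lo, hi]` with the endpoints added to the grid. Adding any affine
#' function of wavenumber to the spectrum leaves the result unchanged
#' (the chord absorbs it). Negative areas are floored at zero.
#'
#' @param s an [ftir_spectrum()]
#' @param region a [band_region()] inside the grid span
#' @return band area, AU cm^-1 (>= 0)
#' @export
integrate_band <- function(s, region) {
  stopifnot(inherits(s, "ftir_spectrum"), inherits(region, "band_region"))
  nu <- s$wavenumber
  if (region$lo < nu[1L] || region$hi > nu[length(nu)])
    stop_cfg("integrate_band: region [%g, %g] outside grid span [%g, %g]",
             region$lo, region$hi, nu[1L], nu[length(nu)])
  a_lo <- interp_abs(s, region$lo)
  a_hi <- interp_abs(s, region$hi)
  inside <- nu > region$lo & nu < region$hi
  x <- c(region$lo, nu[inside], region$hi)
  y <- c(a_lo, s$absorbance[inside], a_hi)
  chord <- a_lo + (a_hi - a_lo) * (x - region$lo) / (region$hi - region$lo)
  max(0, trapz(x, y - chord))
}

# Savitzky-Golay smoothing: least-squares local polynomial of given order
# over a centered odd window; edges use the polynomial fitted at the ends.
savitzky_golay <- function(y, window = 9L, order = 2L) {
  window <- as.integer(window)
  if (window %% 2L == 0L) window <- window + 1L
  n <- length(y)
  if (window > n)
    stop_cfg("savitzky_golay: window (%d) exceeds signal length (%d)",
             window, n)
  if (window <= order + 1L) return(y)
  half <- (window - 1L) %/% 2L
  j <- (-half):half
  A <- outer(j, 0:order, `^`)
  # projection row for the window center
  H <- A %*% solve(crossprod(A), t(A))
  out <- y
  for (i in seq_len(n)) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    if (i - lo == half && hi - i == half) {
      out[i] <- H[half + 1L, ] %*% y[lo:hi]
    } else {
      # edge: refit on the truncated window
      jj <- (lo:hi) - i
      Ae <- outer(jj, 0:order, `^`)
      cf <- solve(crossprod(Ae), crossprod(Ae, y[lo:hi]))
      out[i] <- cf[1L]
    }
  }
  out
}

#' Locate the carbonyl-ester peak inside a band region
#'
#' Works on the chord-subtracted signal inside the region (so baseline tilt
#' cannot masquerade as a peak), applies Savitzky-Golay smoothing
#' (polynomial order 2), and returns the wavenumber of the maximum when its
#' smoothed chord-subtracted height reaches `min_prominence`; otherwise
#' `NA` (no detectable ester band).
#'
#' @param s a normalized [ftir_spectrum()]
#' @param region [band_region()] to search (typically the carbonyl window)
#' @param smooth_window odd window length in grid points
#' @param min_prominence minimum chord-subtracted height, AU
#' @return peak wavenumber (cm^-1) or `NA_real_`
#' @export
find_carbonyl_peak <- function(s, region, smooth_window = 9L,
                               min_prominence = 0.005) {
  stopifnot(inherits(s, "ftir_spectrum"), inherits(region, "band_region"))
  nu <- s$wavenumber
  inside <- nu >= region$lo & nu <= region$hi
  if (sum(inside) < smooth_window)
    stop_cfg("find_carbonyl_peak: smooth_window (%d) exceeds %d points in region",
             smooth_window, sum(inside))
  a_lo <- interp_abs(s, region$lo)
  a_hi <- interp_abs(s, region$hi)
  x <- nu[inside]
  chord <- a_lo + (a_hi - a_lo) * (x - region$lo) / (region$hi - region$lo)
  net <- s$absorbance[inside] - chord
  sm <- savitzky_golay(net, window = smooth_window, order = 2L)
  i <- which.max(sm)
  if (!is.finite(sm[i]) || sm[i] < min_prominence) return(NA_real_)
  x[i]
}

#' Classify PHA side-chain length from the carbonyl peak position
#'
#' The ester carbonyl of crystalline short-chain-length PHA (e.g. PHB)
#' absorbs near 1723--1728 cm^-1, while the more amorphous
#' medium-chain-length polymers absorb near 1738--1741 cm^-1. The default
#' boundary, 1733 cm^-1, is the midpoint of those two regimes.
#'
#' @param peak peak wavenumber (cm^-1) or `NA`
#' @param boundary class boundary, cm^-1; peaks <= boundary are scl
#' @return `"scl"`, `"mcl"`, or `"none"`
#' @export
classify_pha <- function(peak, boundary = 1733) {
  if (length(peak) != 1L) return(vapply(peak, classify_pha, "",
                                        boundary = boundary))
  if (is.na(peak)) return("none")
  if (peak <= boundary) "scl" else "mcl"
}

#' Compute the carbonyl-to-amide-I (CA1) ratio for one spectrum
#'
#' Full per-spectrum chain, in order: amide I anchor normalization, global
#' linear baseline correction, individual-baseline integration of the
#' carbonyl-ester and amide I regions, carbonyl peak localization, and
#' scl/mcl classification. The CA1 ratio (carbonyl area / amide I area) is
#' a relative measure of PHA per cell protein; the whole chain is invariant
#' to positive scaling of the raw spectrum.
#'
#' @param s a raw [ftir_spectrum()]
#' @param profile an [instrument_profile()]
#' @param smooth_window,min_prominence passed to [find_carbonyl_peak()]
#' @param boundary passed to [classify_pha()]
#' @return object of class `ca1_result`: list with `sample_id`,
#'   `carbonyl_area`, `amide1_area`, `ca1_ratio`, `carbonyl_peak`,
#'   `pha_class`
#' @export
compute_ca1 <- function(s, profile = instrument_profile("cary"),
                        smooth_window = 9L, min_prominence = 0.005,
                        boundary = 1733) {
  sn <- normalize_spectrum(s, profile)
  sb <- baseline_correct_linear(sn)
  carbonyl <- integrate_band(sb, profile$carbonyl_region)
  amide1 <- integrate_band(sb, profile$amide1_region)
  if (amide1 <= 0)
    stop_cfg("compute_ca1 [%s]: amide I area %g is not > 0 (no protein signal)",
             s$sample_id, amide1)
  peak <- find_carbonyl_peak(sb, profile$carbonyl_region,
                             smooth_window = smooth_window,
                             min_prominence = min_prominence)
  structure(list(sample_id = s$sample_id,
                 instrument = profile$name,
                 carbonyl_area = carbonyl,
                 amide1_area = amide1,
                 ca1_ratio = carbonyl / amide1,
                 carbonyl_peak = peak,
                 pha_class = classify_pha(peak, boundary)),
            class = "ca1_result")
}

#' @export
print.ca1_result <- function(x, ...) {
  cat(sprintf("<ca1_result> %s: CA1 = %.4g, peak = %s, class = %s\n",
              x$sample_id, x$ca1_ratio,
              if (is.na(x$carbonyl_peak)) "none" else
                sprintf("%g cm-1", x$carbonyl_peak),
              x$pha_class))
  invisible(x)
}

#' Flatten CA1 results into a tidy data frame
#' @param results list of `ca1_result` objects
#' @return data frame, one row per result
#' @export
ca1_table <- function(results) {
  if (inherits(results, "ca1_result")) results <- list(results)
  do.call(rbind, lapply(results, function(r)
    data.frame(sample_id = r$sample_id, instrument = r$instrument,
               carbonyl_area = r$carbonyl_area, amide1_area = r$amide1_area,
               ca1_ratio = r$ca1_ratio, carbonyl_peak_cm1 = r$carbonyl_peak,
               pha_class = r$pha_class)))
}

#' Summarize CA1 ratios per group with box-plot statistics
#'
#' Per group: mean, sample SD (n-1; `NA` for singletons, never reported as
#' 0), median, quartiles by the linear-interpolation method, and box-plot
#' fences at 1.5 IQR.
#'
#' @param results list of `ca1_result` or a data frame with `ca1_ratio`
#' @param group grouping vector (e.g. substrate), recycled against results
#' @return data frame of per-group summaries
#' @export
aggregate_ca1 <- function(results, group) {
  df <- if (is.data.frame(results)) results else ca1_table(results)
  if (nrow(df) == 0L) stop_cfg("aggregate_ca1: no results")
  if (length(group) != nrow(df))
    stop_cfg("aggregate_ca1: group length %d != %d results",
             length(group), nrow(df))
  out <- lapply(split(df$ca1_ratio, group), function(v) {
    if (!length(v)) stop_cfg("aggregate_ca1: empty group")
    q <- quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    iqr <- q[3L] - q[1L]
    data.frame(n = length(v), mean = mean(v),
               sd = if (length(v) > 1L) sd(v) else NA_real_,
               median = q[2L], q1 = q[1L], q3 = q[3L],
               lower_fence = q[1L] - 1.5 * iqr,
               upper_fence = q[3L] + 1.5 * iqr)
  })
  res <- do.call(rbind, out)
  res <- cbind(group = names(out), res)
  rownames(res) <- NULL
  res
}
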