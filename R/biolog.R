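#' Construct a 96-well kinetic plate
#'
#' Time-resolved absorbance for a whole plate on one shared time grid, with
#' a well-to-substrate layout and a designated no-carbon control well.
#'
#' @param times hours, strictly increasing
#' @param values numeric matrix, `length(times)` rows, one named column per
#'   well
#' @param layout data frame with columns `well` and `substrate` (optional
#'   `role`)
#' @param control_well no-carbon control well id, must be in the layout
#' @return object of class `kinetic_plate`
#' @export
kinetic_plate <- function(times, values, layout, control_well = "A1") {
  times <- as.numeric(times)
  values <- as.matrix(values)
  if (any(diff(times) <= 0))
    stop_cfg("kinetic_plate: times must be strictly increasing")
  if (nrow(values) != length(times))
    stop_cfg("kinetic_plate: %d rows of values vs %d times",
             nrow(values), length(times))
  if (is.null(colnames(values)))
    stop_cfg("kinetic_plate: value columns must be named by well")
  layout <- as.data.frame(layout)
  if (!all(c("well", "substrate") %in% names(layout)))
    stop_cfg("kinetic_plate: layout needs well and substrate columns")
  if (!control_well %in% layout$well)
    stop_cfg("kinetic_plate: control well %s absent from layout",
             control_well)
  if (!control_well %in% colnames(values))
    stop_cfg("kinetic_plate: control well %s absent from plate columns",
             control_well)
  structure(list(times = times, values = values, layout = layout,
                 control_well = control_well,
                 background_subtracted = FALSE),
            class = "kinetic_plate")
}

#' @export
print.kinetic_plate <- function(x, ...) {
  cat(sprintf("<kinetic_plate> %d wells x %d timepoints (%g-%g h), control %s%s\n",
              ncol(x$values), length(x$times), min(x$times), max(x$times),
              x$control_well,
              if (x$background_subtracted) ", background-subtracted" else ""))
  invisible(x)
}

#' The standard Biolog PM1 well-to-substrate map
#'
#' 95 carbon sources plus the A1 negative (no carbon) control, in the
#' manufacturer's standard arrangement; shipped as a plain-text table.
#'
#' @return data frame with columns `well`, `substrate`, `role`
#' @export
pm1_layout <- function() {
  path <- system.file("extdata", "pm1_layout.csv", package = "phascreen",
                      mustWork = TRUE)
  read.csv(path, stringsAsFactors = FALSE)
}

#' Read a plate from per-timepoint 8 x 12 grid exports
#'
#' Some plate readers export one file per read, as an 8-row (A-H) by
#' 12-column grid of absorbances, optionally with a leading row-letter
#' column and a header row of column numbers. Files are combined into one
#' [kinetic_plate()] on the supplied time grid.
#'
#' @param files one CSV per timepoint, in time order
#' @param times matching acquisition times, hours
#' @param layout,control_well as in [kinetic_plate()]
#' @return a [kinetic_plate()]
#' @export
read_biolog_grids <- function(files, times, layout = NULL,
                              control_well = "A1") {
  if (length(files) != length(times))
    stop_cfg("read_biolog_grids: %d files but %d times",
             length(files), length(times))
  read_grid <- function(path) {
    raw <- read.csv(path, header = FALSE, stringsAsFactors = FALSE,
                    colClasses = "character")
    # drop a leading row-letter column (its header cell, if any, may be
    # blank or a label)
    if (ncol(raw) == 13L && all(utils::tail(raw[[1L]], 8L) %in%
                                LETTERS[1:8]))
      raw <- raw[, -1L, drop = FALSE]
    # drop a header row of column numbers
    first <- suppressWarnings(as.numeric(raw[1L, ]))
    if (nrow(raw) == 9L && !anyNA(first) && all(first == 1:12))
      raw <- raw[-1L, , drop = FALSE]
    m <- suppressWarnings(matrix(as.numeric(as.matrix(raw)), nrow(raw)))
    if (!all(dim(m) == c(8L, 12L)) || anyNA(m))
      stop_cfg("%s: expected a numeric 8 x 12 well grid", path)
    as.vector(t(m))  # row-major: A1..A12, B1.., matching well_ids_96()
  }
  vals <- t(vapply(files, read_grid, numeric(96L)))
  colnames(vals) <- well_ids_96()
  rownames(vals) <- NULL
  if (is.null(layout)) layout <- pm1_layout()
  kinetic_plate(as.numeric(times), vals, layout = layout,
                control_well = control_well)
}

#' Subtract the no-carbon control trace from every well
#'
#' The control well's formazan background (abiotic dye reduction plus
#' turbidity drift) is subtracted timepoint-by-timepoint from each well;
#' the control itself becomes exactly zero.
#'
#' @param plate a [kinetic_plate()]
#' @return background-subtracted [kinetic_plate()]
#' @export
subtract_background <- function(plate) {
  stopifnot(inherits(plate, "kinetic_plate"))
  ctrl <- plate$values[, plate$control_well]
  if (anyNA(ctrl))
    stop_cfg("subtract_background: control series has missing values")
  plate$values <- sweep(plate$values, 1L, ctrl, `-`)
  plate$background_subtracted <- TRUE
  plate
}

#' Average replicate plates pointwise
#'
#' Plates must share the time grid, well set, and layout; the mean is taken
#' per well per timepoint (independent replicate experiments).
#'
#' @param plates list of [kinetic_plate()]
#' @return a [kinetic_plate()] of pointwise means
#' @export
average_plates <- function(plates) {
  if (inherits(plates, "kinetic_plate")) plates <- list(plates)
  if (!length(plates)) stop_cfg("average_plates: no plates")
  ref <- plates[[1L]]
  for (p in plates[-1L]) {
    if (!isTRUE(all.equal(p$times, ref$times)))
      stop_cfg("average_plates: time grids differ")
    if (!identical(sort(colnames(p$values)), sort(colnames(ref$values))))
      stop_cfg("average_plates: well sets differ")
    if (!identical(p$layout[order(p$layout$well), c("well", "substrate")],
                   ref$layout[order(ref$layout$well), c("well", "substrate")]))
      stop_cfg("average_plates: layouts differ")
  }
  acc <- Reduce(`+`, lapply(plates, function(p)
    p$values[, colnames(ref$values), drop = FALSE]))
  ref$values <- acc / length(plates)
  ref$background_subtracted <-
    all(vapply(plates, `[[`, TRUE, "background_subtracted"))
  ref
}

#' Classify substrates as metabolized at one or more absorbance cutoffs
#'
#' A substrate counts as metabolized at cutoff c when the maximum of its
#' background-subtracted (net) series over all timepoints strictly exceeds
#' c ("exceeding" the threshold; a value equal to the cutoff does not
#' count). The control well is excluded. Counts are monotone non-increasing
#' in the cutoff by construction.
#'
#' @param plate a background-subtracted (and, if replicated, averaged)
#'   [kinetic_plate()]
#' @param cutoffs net-absorbance thresholds, AU
#' @return data frame with `well`, `substrate`, `max_net_abs` and one
#'   logical `metabolized_<cutoff>` column per cutoff; per-cutoff counts
#'   in the `"counts"` attribute
#' @export
classify_substrates <- function(plate, cutoffs = c(0.15, 0.30, 1.00)) {
  stopifnot(inherits(plate, "kinetic_plate"))
  if (!plate$background_subtracted)
    warning("classify_substrates: plate is not background-subtracted")
  wells <- setdiff(colnames(plate$values), plate$control_well)
  mx <- apply(plate$values[, wells, drop = FALSE], 2L, max)
  sub <- plate$layout$substrate[match(wells, plate$layout$well)]
  out <- data.frame(well = wells, substrate = sub, max_net_abs = mx,
                    row.names = NULL)
  for (c in cutoffs) out[[sprintf("metabolized_%g", c)]] <- mx > c
  counts <- vapply(cutoffs, function(c) sum(mx > c), 1L)
  names(counts) <- sprintf("%g", cutoffs)
  attr(out, "counts") <- counts
  out
}

#' Per-cutoff metabolized-substrate counts
#' @param calls result of [classify_substrates()]
#' @return named integer vector of counts
#' @export
substrate_counts <- function(calls) attr(calls, "counts")

#' Export a substrate-by-timepoint net-absorbance heatmap matrix
#'
#' Builds the matrix underlying the screening heatmaps: rows follow the
#' requested substrate order, columns the requested timepoints. Negative
#' net values are retained in the matrix (flooring is a display concern
#' only). Optionally writes a CSV and renders with pheatmap if available.
#'
#' @param plate a background-subtracted [kinetic_plate()]
#' @param substrates subset of layout substrates (default: all non-control)
#' @param timepoints subset of `plate$times` (default: all)
#' @param csv optional output CSV path
#' @param render draw with pheatmap when available
#' @return the numeric matrix, invisibly when `csv` is written
#' @export
export_heatmap <- function(plate, substrates = NULL, timepoints = NULL,
                           csv = NULL, render = FALSE) {
  stopifnot(inherits(plate, "kinetic_plate"))
  lay <- plate$layout[plate$layout$well != plate$control_well, ]
  if (is.null(substrates)) substrates <- lay$substrate
  unknown <- setdiff(substrates, lay$substrate)
  if (length(unknown))
    stop_cfg("export_heatmap: unknown substrate(s) %s; valid: %s",
             paste(unknown, collapse = ", "),
             paste(utils::head(sort(lay$substrate), 12L), collapse = ", "))
  if (is.null(timepoints)) timepoints <- plate$times
  ti <- match(timepoints, plate$times)
  if (anyNA(ti))
    stop_cfg("export_heatmap: timepoint(s) not on the grid: %s",
             paste(timepoints[is.na(ti)], collapse = ", "))
  wells <- lay$well[match(substrates, lay$substrate)]
  m <- t(plate$values[ti, wells, drop = FALSE])
  dimnames(m) <- list(substrates, sprintf("%g", plate$times[ti]))
  if (!is.null(csv))
    write.csv(data.frame(substrate = rownames(m), m, check.names = FALSE),
              csv, row.names = FALSE)
  if (render && requireNamespace("pheatmap", quietly = TRUE))
    pheatmap::pheatmap(pmax(m, 0), cluster_rows = FALSE,
                       cluster_cols = FALSE)
  if (is.null(csv)) m else invisible(m)
}
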