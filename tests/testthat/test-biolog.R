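make_net_plate <- function(amplitudes, noise_sd = 0, seed = 1L) {
  pw <- data.frame(well = well_ids_96(), amplitude = amplitudes)
  subtract_background(generate_biolog_plate(pw, control_well = "A1",
                                            noise_sd = noise_sd,
                                            seed = seed))
}

test_that("subtract_background zeroes the control and removes shifts", {
  pw <- data.frame(well = well_ids_96(), amplitude = 0)
  plate <- generate_biolog_plate(pw, noise_sd = 0)
  # add a constant offset to one well: net must be exactly that constant
  plate$values[, "B3"] <- plate$values[, "A1"] + 0.2
  net <- subtract_background(plate)
  expect_true(all(net$values[, "A1"] == 0))
  expect_true(all(abs(net$values[, "B3"] - 0.2) < 1e-12))
})

test_that("average_plates is a pointwise mean and checks compatibility", {
  pw <- data.frame(well = well_ids_96(), amplitude = 0.5)
  p1 <- generate_biolog_plate(pw, noise_sd = 0.01, seed = 1L)
  p2 <- generate_biolog_plate(pw, noise_sd = 0.01, seed = 2L)
  avg <- average_plates(list(p1, p2))
  expect_equal(avg$values, (p1$values + p2$values) / 2)
  expect_equal(average_plates(list(p1, p1, p1))$values, p1$values,
               tolerance = 1e-14)

  # mean of k replicates shrinks noise ~ 1/sqrt(k)
  plates <- lapply(1:3, function(s)
    generate_biolog_plate(pw, noise_sd = 0.05, seed = 10L + s))
  avg3 <- average_plates(plates)
  clean <- generate_biolog_plate(pw, noise_sd = 0)
  sd1 <- sd(plates[[1L]]$values - clean$values)
  sd3 <- sd(avg3$values - clean$values)
  expect_rel(sd3, sd1 / sqrt(3), 0.1)

  bad <- p2
  bad$layout$substrate[2L] <- "something else"
  expect_error(average_plates(list(p1, bad)), "layouts differ")
})

test_that("classify_substrates uses a strict cutoff on the net maximum", {
  amp <- rep(0, 96L)
  amp[2L] <- 0.16   # just above the low cutoff
  amp[3L] <- 0.15   # exactly at it: NOT metabolized
  net <- make_net_plate(amp)
  # logistic-like accumulation slightly undershoots the amplitude; give
  # the boundary well its exact plateau value
  net$values[nrow(net$values), 3L] <- 0.15
  calls <- classify_substrates(net, cutoffs = 0.15)
  expect_true(calls$metabolized_0.15[calls$well == "A2"])
  expect_false(calls$metabolized_0.15[calls$well == "A3"])

  # count monotonicity across the standard cutoffs
  amp2 <- withr::with_seed(7L, runif(96L, 0, 1.6))
  cts <- substrate_counts(classify_substrates(make_net_plate(amp2)))
  expect_true(cts[["1"]] <= cts[["0.3"]] && cts[["0.3"]] <= cts[["0.15"]])

  # order of timepoints cannot matter: max is permutation-invariant
  net2 <- make_net_plate(amp2)
  perm <- withr::with_seed(8L, sample(nrow(net2$values)))
  shuffled_max <- apply(net2$values[perm, ], 2L, max)
  expect_equal(unname(shuffled_max), unname(apply(net2$values, 2L, max)))
})

test_that("subtract-then-average equals average-then-subtract", {
  pw <- data.frame(well = well_ids_96(),
                   amplitude = rep(c(0, 0.3, 0.8, 1.4), 24L))
  plates <- lapply(1:3, function(s)
    generate_biolog_plate(pw, noise_sd = 0.01, seed = 20L + s))
  a <- average_plates(lapply(plates, subtract_background))
  b <- subtract_background(average_plates(plates))
  expect_equal(a$values, b$values, tolerance = 1e-12)
})

test_that("export_heatmap builds the requested matrix and validates names", {
  amp <- rep(0, 96L); amp[c(2L, 3L)] <- c(0.4, 1.2)
  net <- make_net_plate(amp)
  lay <- net$layout
  subs <- lay$substrate[match(c("A3", "A2"), lay$well)]
  m <- export_heatmap(net, substrates = subs, timepoints = net$times[25L])
  expect_equal(dim(m), c(2L, 1L))
  expect_identical(rownames(m), subs)  # requested order preserved
  expect_equal(m[1L, 1L], unname(net$values[25L, "A3"]))

  full <- export_heatmap(net)
  expect_equal(max(full), max(net$values[, colnames(net$values) != "A1"]))
  expect_error(export_heatmap(net, substrates = "Unobtainium"),
               "unknown substrate")

  csvf <- withr::local_tempfile(fileext = ".csv")
  export_heatmap(net, csv = csvf)
  expect_true(file.exists(csvf))
})

test_that("read_biolog_grids assembles per-timepoint 8x12 exports", {
  pw <- data.frame(well = well_ids_96(),
                   amplitude = rep(c(0, 0.3, 0.8, 1.4), 24L))
  plate <- generate_biolog_plate(pw, noise_sd = 0, t_end = 48, step = 24)
  td <- withr::local_tempdir()
  files <- character(0)
  for (i in seq_along(plate$times)) {
    grid <- matrix(plate$values[i, ], nrow = 8L, byrow = TRUE)
    f <- file.path(td, sprintf("read_%02d.csv", i))
    if (i %% 2L == 0L) {
      # decorated dialect: column-number header + row-letter column
      rows <- vapply(1:8, function(r)
        paste(c(LETTERS[r], sprintf("%.17g", grid[r, ])), collapse = ","),
        "")
      writeLines(c(paste(c("", 1:12), collapse = ","), rows), f)
    } else {
      write.table(grid, f, sep = ",", row.names = FALSE,
                  col.names = FALSE)
    }
    files <- c(files, f)
  }
  back <- read_biolog_grids(files, plate$times)
  expect_equal(back$values, plate$values, tolerance = 1e-12)
  expect_equal(substrate_counts(classify_substrates(
    subtract_background(back))),
    substrate_counts(classify_substrates(subtract_background(plate))))

  badf <- file.path(td, "bad.csv")
  writeLines(c("1,2", "3,4"), badf)
  expect_error(read_biolog_grids(badf, 0), "8 x 12")
  expect_error(read_biolog_grids(files, 1:2), "files but")
})

test_that("plate CSV round-trips through write_plate_csv/read_kinetic_plate", {
  pw <- data.frame(well = well_ids_96(), amplitude = 0.4)
  plate <- generate_biolog_plate(pw, noise_sd = 0.01, seed = 3L)
  f <- withr::local_tempfile(fileext = ".csv")
  write_plate_csv(plate, f)
  back <- read_kinetic_plate(f)
  expect_equal(back$times, plate$times)
  expect_equal(back$values, plate$values, tolerance = 1e-12)
  expect_identical(back$control_well, "A1")
})
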