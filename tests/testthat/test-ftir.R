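cary <- instrument_profile("cary")

test_that("read_spectrum rejects malformed files with line numbers", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("wavenumber_cm-1,absorbance", "1000,0.1", "1000,0.2",
               "1004,0.1", "1006,0.1", "1008,0.1", "1010,0.1", "1012,0.1",
               "1014,0.1"), f)
  expect_error(read_spectrum(f), "duplicated wavenumber 1000")

  writeLines(c("wavenumber_cm-1,absorbance", "1000,0.1", "1002,abc",
               "1004,0.1"), f)
  expect_error(read_spectrum(f), "non-numeric value at line 3")

  writeLines(c("wavenumber_cm-1,absorbance", "1000,0.1", "1004,0.2",
               "1002,0.1", "1006,0.1", "1008,0.1", "1010,0.1", "1012,0.1",
               "1014,0.1"), f)
  expect_error(read_spectrum(f), "non-monotone")

  expect_error(read_spectrum("no/such/file.csv"), "no such file")
})

test_that("read_spectrum parses AFFN JCAMP-DX point tables", {
  f <- withr::local_tempfile(fileext = ".jdx")
  nu <- seq(1000, 1014, 2)
  ab <- seq(0.1, 0.8, 0.1)
  writeLines(c("##TITLE=synthetic", "##JCAMP-DX=4.24", "##XUNITS=1/CM",
               "##XFACTOR=1", "##YFACTOR=0.1",
               "##XYPOINTS=(XY..XY)",
               paste(nu, ab * 10, collapse = " "),
               "##END="), f)
  sp <- read_spectrum(f)
  expect_equal(sp$wavenumber, nu)
  expect_equal(sp$absorbance, ab)

  f2 <- withr::local_tempfile(fileext = ".jdx")
  writeLines(c("##TITLE=synthetic", "##DELTAX=2", "##XFACTOR=1",
               "##YFACTOR=1", "##XYDATA=(X++(Y..Y))",
               "1000 0.1 0.2 0.3 0.4", "1008 0.5 0.6 0.7 0.8",
               "##END="), f2)
  sp2 <- read_spectrum(f2, format = "jcamp")
  expect_equal(sp2$wavenumber, nu)
  expect_equal(sp2$absorbance, ab)
})

test_that("normalize_spectrum: anchor definition, idempotence, scale invariance", {
  sp <- generate_spectrum(list(band_spec(1650, 0.5, 40),
                               band_spec(1728, 0.2, 20)),
                          sim_config(seed = 2L, noise_sd = 0.003,
                                     baseline_offset = 0.75))
  n1 <- normalize_spectrum(sp, cary)
  a1650 <- approx(n1$wavenumber, n1$absorbance, xout = 1650)$y
  expect_equal(a1650, 0.5)

  # idempotence to machine precision
  n2 <- normalize_spectrum(n1, cary)
  expect_equal(n2$absorbance, n1$absorbance, tolerance = 1e-14)

  # scaling the raw spectrum by any c > 0 changes nothing post-normalization
  for (c in c(0.2, 3, 57)) {
    sc <- sp; sc$absorbance <- sc$absorbance * c
    expect_equal(normalize_spectrum(sc, cary)$absorbance, n1$absorbance,
                 tolerance = 1e-12)
  }

  blank <- generate_spectrum(list(), sim_config(baseline_offset = 0))
  expect_error(normalize_spectrum(blank, cary), "not > 0")
})

test_that("baseline_correct_linear zeroes endpoints and kills affine spectra", {
  aff <- generate_spectrum(list(), sim_config(baseline_offset = 0.3,
                                              baseline_slope = 2e-4))
  bc <- baseline_correct_linear(aff)
  expect_true(all(abs(bc$absorbance) < 1e-12))

  sp <- generate_spectrum(list(band_spec(1650, 0.5, 40)),
                          sim_config(baseline_offset = 0.1,
                                     baseline_slope = 1e-4))
  bc <- baseline_correct_linear(sp)
  expect_equal(bc$absorbance[1L], 0)
  expect_equal(bc$absorbance[length(bc$absorbance)], 0)
  # residual equals the pure band minus the chord through the band's
  # values at the spectrum endpoints (zero here: band vanishes at ends)
  pure <- generate_spectrum(list(band_spec(1650, 0.5, 40)), sim_config())
  expect_equal(bc$absorbance, pure$absorbance, tolerance = 1e-10)
})

test_that("integrate_band matches the continuous chord oracle and is affine-invariant", {
  # spec example geometry (1728, 0.2, 20), Cary carbonyl region: the
  # continuous oracle gives 4.093943; tail+chord loss puts it 3.85% below
  # the closed form 4.257868
  sp <- generate_spectrum(list(band_spec(1728, 0.2, 20)), sim_config())
  a <- integrate_band(sp, cary$carbonyl_region)
  oracle <- oracle_chord_area(gauss_band_fn(1728, 0.2, 20), 1705, 1763)
  expect_rel(oracle, 4.093943, 1e-6)
  expect_rel(a, oracle, 0.01)
  expect_rel(a, gauss_closed_area(0.2, 20), 0.045)

  # band centered mid-region is fully inside: within 2% of closed form
  spc <- generate_spectrum(list(band_spec(1734, 0.2, 20)), sim_config())
  expect_rel(integrate_band(spc, cary$carbonyl_region),
             gauss_closed_area(0.2, 20), 0.02)

  # affine spectra integrate to exactly zero
  aff <- generate_spectrum(list(), sim_config(baseline_offset = 0.4,
                                              baseline_slope = -1e-4))
  expect_equal(integrate_band(aff, cary$carbonyl_region), 0)

  # affine invariance on random perturbations (floor prevents negatives)
  withr::with_seed(42L, for (i in 1:10) {
    off <- runif(1, -0.5, 0.5); slp <- runif(1, -5e-4, 5e-4)
    pert <- sp
    pert$absorbance <- pert$absorbance + off + slp * pert$wavenumber
    expect_equal(integrate_band(pert, cary$carbonyl_region), a,
                 tolerance = 1e-9)
  })

  expect_error(integrate_band(sp, band_region("x", 100, 200)),
               "outside grid span")
})

test_that("find_carbonyl_peak localizes, thresholds, and ignores tilt", {
  sp <- generate_spectrum(list(band_spec(1650, 0.5, 40),
                               band_spec(1728, 0.2, 20)),
                          sim_config(baseline_slope = 2e-4))
  pk <- find_carbonyl_peak(sp, cary$carbonyl_region)
  expect_lte(abs(pk - 1728), 2)  # grid step

  flat <- generate_spectrum(list(band_spec(1650, 0.5, 40)), sim_config())
  expect_true(is.na(find_carbonyl_peak(flat, cary$carbonyl_region)))

  faint <- generate_spectrum(list(band_spec(1728, 0.003, 20)), sim_config())
  expect_true(is.na(find_carbonyl_peak(faint, cary$carbonyl_region)))

  expect_error(find_carbonyl_peak(sp, cary$carbonyl_region,
                                  smooth_window = 999L), "exceeds")
})

test_that("compute_ca1: frozen oracle value, scale invariance, monotonicity", {
  bands <- list(band_spec(1650, 0.5, 40), band_spec(1728, 0.2, 20))
  sp <- generate_spectrum(bands, sim_config())
  r <- compute_ca1(sp, cary)
  # continuous-oracle CA1 for this geometry = 0.193759 (3.1% below the
  # naive closed-form ratio 0.200 from edge-tail/chord loss)
  oracle <- oracle_ca1(list(gauss_band_fn(1650, 0.5, 40),
                            gauss_band_fn(1728, 0.2, 20)))
  expect_rel(oracle, 0.193759, 1e-5)
  expect_rel(r$ca1_ratio, oracle, 0.01)
  expect_rel(r$ca1_ratio, 0.2, 0.04)
  expect_identical(r$pha_class, "scl")

  # no carbonyl -> zero area, class none
  r0 <- compute_ca1(generate_spectrum(bands[1L], sim_config()), cary)
  expect_equal(r0$carbonyl_area, 0)
  expect_equal(r0$ca1_ratio, 0)
  expect_identical(r0$pha_class, "none")
  expect_true(is.na(r0$carbonyl_peak))

  # raw-scale invariance of the whole chain
  for (c in c(0.5, 4)) {
    sc <- sp; sc$absorbance <- sc$absorbance * c
    rc <- compute_ca1(sc, cary)
    expect_equal(rc$ca1_ratio, r$ca1_ratio, tolerance = 1e-10)
    expect_equal(rc$carbonyl_peak, r$carbonyl_peak)
  }

  # strictly increasing in carbonyl height
  heights <- c(0.05, 0.1, 0.2, 0.4, 0.8)
  ratios <- vapply(heights, function(h) {
    s <- generate_spectrum(list(band_spec(1650, 0.5, 40),
                                band_spec(1728, h, 20)), sim_config())
    compute_ca1(s, cary)$ca1_ratio
  }, 1.0)
  expect_true(all(diff(ratios) > 0))
})

test_that("classify_pha boundary semantics match the reported peak regimes", {
  expect_identical(classify_pha(1728), "scl")
  expect_identical(classify_pha(1738), "mcl")
  expect_identical(classify_pha(1723), "scl")
  expect_identical(classify_pha(1733), "scl")   # boundary inclusive to scl
  expect_identical(classify_pha(NA_real_), "none")
  expect_identical(classify_pha(1738, boundary = 1740), "scl")
})

test_that("aggregate_ca1 computes box-plot statistics with n-1 SD", {
  mk <- function(v, g) data.frame(ca1_ratio = v, sample_id = seq_along(v))
  s <- aggregate_ca1(mk(c(0.2, 0.2, 0.2)), rep("a", 3L))
  expect_equal(s$mean, 0.2)
  expect_equal(s$sd, 0)

  s2 <- aggregate_ca1(mk(1:4), rep("b", 4L))
  expect_equal(s2$median, 2.5)
  expect_equal(s2$q1, 1.75)
  expect_equal(s2$q3, 3.25)
  expect_equal(s2$lower_fence, 1.75 - 1.5 * 1.5)
  expect_equal(s2$upper_fence, 3.25 + 1.5 * 1.5)

  # singleton: SD is missing, not zero
  s3 <- aggregate_ca1(mk(0.7), "c")
  expect_equal(s3$mean, 0.7)
  expect_true(is.na(s3$sd))
})
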