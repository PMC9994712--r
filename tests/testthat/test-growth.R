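test_that("fit_growth_curve recovers logistic rate and AUC (closed-form oracles)", {
  # analytic max of d ln N / dt is r (1 - N0/K) = 0.225 at t = lag
  gc <- generate_growth_curve(K = 1.5, N0 = 0.15, r = 0.25, lag_h = 0,
                              t_end = 48, step = 0.25, noise_sd = 0)
  m <- fit_growth_curve(gc)
  expect_rel(m$gr, 0.225, 0.10)
  expect_rel(m$auc, logistic_auc(1.5, 0.15, 0.25, 48), 0.01)
  expect_lt(m$mse, 1e-6)
  expect_true(m$t_gr >= min(gc$times) && m$t_gr <= max(gc$times))

  # constant OD: gr 0, auc = 0.2 * 10, flagged degenerate
  cst <- growth_curve(seq(0, 10, length.out = 41L), rep(0.2, 41L))
  mc <- fit_growth_curve(cst)
  expect_equal(mc$gr, 0)
  expect_equal(mc$auc, 2.0)
  expect_equal(mc$mse, 0)
  expect_true(mc$flagged)

  expect_error(fit_growth_curve(growth_curve(1:5, rep(0.2, 5))),
               ">= 10 time points")
})

test_that("noisy growth-rate recovery: mean gr within 15% over 20 seeds", {
  grs <- vapply(1:20, function(s) {
    gc <- generate_growth_curve(K = 1.5, N0 = 0.15, r = 0.25, lag_h = 0,
                                t_end = 48, step = 0.25, noise_sd = 0.01,
                                seed = s)
    fit_growth_curve(gc)$gr
  }, 1.0)
  expect_rel(mean(grs), 0.225, 0.15)
})

test_that("parameter recovery across rates: median relative error < 15%", {
  for (r in c(0.1, 0.2, 0.3)) {
    truth <- r * (1 - 0.15 / 1.5)
    err <- vapply(1:10, function(s) {
      gc <- generate_growth_curve(K = 1.5, N0 = 0.15, r = r, lag_h = 0,
                                  t_end = 48, step = 0.25,
                                  noise_sd = 0.01, seed = 100L + s)
      abs(fit_growth_curve(gc)$gr - truth) / truth
    }, 1.0)
    expect_lt(median(err), 0.15)
  }
})

test_that("AUC is additive over a split of the time span", {
  gc <- generate_growth_curve(noise_sd = 0.01, seed = 9L)
  mid <- which.min(abs(gc$times - max(gc$times) / 2))
  full <- trapz(gc$times, gc$od)
  left <- trapz(gc$times[1:mid], gc$od[1:mid])
  right <- trapz(gc$times[mid:length(gc$times)], gc$od[mid:length(gc$od)])
  expect_equal(full, left + right, tolerance = 1e-12)
})

test_that("detect_outliers flags by 1.5 IQR fences and is scale-invariant", {
  df <- data.frame(gr = c(0.20, 0.21, 0.19, 0.90),
                   t_gr = rep(5, 4), mse = rep(0.01, 4),
                   auc = rep(50, 4))
  flags <- detect_outliers(df)
  expect_identical(as.logical(flags), c(FALSE, FALSE, FALSE, TRUE))

  # identical metrics: nothing flagged
  same <- data.frame(gr = rep(0.2, 5), t_gr = rep(4, 5),
                     mse = rep(0.01, 5), auc = rep(40, 5))
  expect_false(any(detect_outliers(same)))

  # one extreme mse in otherwise tight data: exactly that curve
  df2 <- data.frame(gr = seq(0.195, 0.205, length.out = 8L),
                    t_gr = seq(4.9, 5.1, length.out = 8L),
                    mse = c(rep(0.01, 7L), 5),
                    auc = seq(49, 51, length.out = 8L))
  expect_identical(which(as.logical(detect_outliers(df2))), 8L)

  # common rescaling leaves flags unchanged
  df3 <- df; df3$gr <- df3$gr * 1000
  expect_identical(as.logical(detect_outliers(df3)), as.logical(flags))

  expect_warning(fl <- detect_outliers(df[1:3, ]), "fewer than 4")
  expect_false(any(fl))
})

test_that("compare_to_control: band rule and Welch t-test", {
  mk <- function(v) data.frame(gr = v)
  same <- compare_to_control(mk(c(0.2, 0.21, 0.19)),
                             mk(c(0.2, 0.21, 0.19)), "gr")
  expect_false(same$outside_band)
  expect_gt(same$p_value, 0.9)

  diffg <- compare_to_control(mk(c(0.22, 0.24, 0.23)),
                              mk(c(0.02, 0.03, 0.025)), "gr")
  expect_true(diffg$outside_band)
  expect_lt(diffg$p_value, 0.05)
  # independent Welch computation
  expect_equal(diffg$p_value,
               t.test(c(0.22, 0.24, 0.23), c(0.02, 0.03, 0.025))$p.value)

  # boundary exactly at 2 SD counts as inside (non-strict)
  ctrl <- c(0.1, 0.2, 0.3)  # mean 0.2, sd 0.1
  bd <- compare_to_control(mk(rep(0.4, 3)), mk(ctrl), "gr")
  expect_false(bd$outside_band)

  single <- compare_to_control(mk(c(0.2, 0.3)), mk(0.1), "gr")
  expect_true(is.na(single$outside_band))
  expect_true(is.na(single$p_value))
})

test_that("gp smoother mirrors the spline metrics on clean data", {
  gc <- generate_growth_curve(K = 1.5, N0 = 0.15, r = 0.25, lag_h = 0,
                              t_end = 48, step = 0.5, noise_sd = 0)
  mg <- fit_growth_curve(gc, smoother = "gp")
  expect_rel(mg$gr, 0.225, 0.15)
  expect_rel(mg$auc, logistic_auc(1.5, 0.15, 0.25, 48), 0.01)
})
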