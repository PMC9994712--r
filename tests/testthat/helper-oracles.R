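# Independent oracles, deliberately not sharing code with the package:
# continuous-math band integrals via stats::integrate on analytic band
# functions, and closed-form logistic identities.

gauss_band_fn <- function(center, height, fwhm) {
  force(center); force(height); force(fwhm)
  function(nu) height * exp(-4 * log(2) * (nu - center)^2 / fwhm^2)
}

sum_fns <- function(fns) function(nu) Reduce(`+`, lapply(fns, function(f) f(nu)))

# chord-subtracted integral of a continuous function over [lo, hi]
oracle_chord_area <- function(f, lo, hi) {
  a <- f(lo); b <- f(hi)
  stats::integrate(function(x) f(x) - (a + (b - a) * (x - lo) / (hi - lo)),
                   lo, hi, rel.tol = 1e-12, subdivisions = 2000L)$value
}

gauss_closed_area <- function(height, fwhm) {
  height * fwhm * sqrt(pi / (4 * log(2)))
}

# full CA1 chain on analytic bands: normalize at anchor, then chord areas
oracle_ca1 <- function(bands, carbonyl = c(1705, 1763),
                       amide = c(1580, 1705), anchor = 1650, target = 0.5) {
  f <- sum_fns(bands)
  sc <- target / f(anchor)
  g <- function(x) sc * f(x)
  oracle_chord_area(g, carbonyl[1L], carbonyl[2L]) /
    oracle_chord_area(g, amide[1L], amide[2L])
}

expect_rel <- function(object, expected, tol) {
  expect_lt(abs(object - expected) / abs(expected), tol)
}
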