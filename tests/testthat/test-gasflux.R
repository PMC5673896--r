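test_that("slope estimation recovers linear and constant series", {
  t <- seq(0, 600, 30)
  ser <- headspaceSeries(t, 4e-4 + 2e-9 * t)
  expect_equal(estimateSlope(ser)$slope, 2e-9, tolerance = 1e-9)
  flat <- headspaceSeries(t, rep(4e-4, length(t)))
  expect_equal(estimateSlope(flat)$slope, 0)
  expect_error(estimateSlope(ser, window = c(0, 31)), "at least 3")
})

test_that("the chamber equation applies the printed unit chain", {
  ch <- chamberSpec(V = 1000, M = 100, Pa = 101.325, T = 295.15,
                    R = 8.3e3)
  # independent dimensional computation of the same quantity
  expected <- 1e-9 * (1000 / 100) * (101.325 / (8.3e3 * 295.15)) * 1e6
  expect_equal(fluxEq1(1e-9, ch), expected)
  expect_equal(fluxEq1(0, ch), 0)
  # scaling law: doubling soil mass halves the flux
  ch2 <- chamberSpec(V = 1000, M = 200, Pa = 101.325, T = 295.15)
  expect_equal(fluxEq1(1e-9, ch2), fluxEq1(1e-9, ch) / 2)
  # negative slopes (uptake) keep their sign
  expect_lt(fluxEq1(-1e-9, ch), 0)
})

test_that("cumulative integration matches closed forms and is additive", {
  ch <- chamberSpec(M = 100)
  # constant 1e-6 umol/g/s over 1000 s and 100 g: 0.1 umol = 1.2011 ug C
  got <- integrateCumulative(c(0, 1000), c(1e-6, 1e-6), ch)
  expect_equal(got, 1.2011, tolerance = 1e-12)
  expect_equal(integrateCumulative(c(0, 1000), c(0, 0), ch), 0)
  t <- seq(0, 1000, 50); f <- 1e-6 * exp(-t / 400)
  whole <- integrateCumulative(t, f, ch)
  parts <- integrateCumulative(t[t <= 500], f[t <= 500], ch) +
    integrateCumulative(t[t >= 500], f[t >= 500], ch)
  expect_equal(whole, parts, tolerance = 1e-12)
  expect_error(integrateCumulative(numeric(), numeric(), ch), "span")
})

test_that("trapezoidal cumulative emission converges under refinement", {
  ch <- chamberSpec()
  A <- birchPulse(1e-5, 2e-3, 14400)
  ce <- function(dt) {
    ser <- genConcentrationSeries(A, ch, duration_min = 400, dt_s = dt)
    cumulativeEmission(ser, ch)$co2_mgC
  }
  expect_lt(abs(ce(30) - ce(15)) / ce(15), 0.001)
})

test_that("flux pipeline inverts the generator within 1 percent", {
  ch <- chamberSpec()
  target <- 245.1                       # mg CO2-C calibration point
  dur_s <- 1400 * 60
  amp <- calibrateBirchAmplitude(target * 1000, ch@M, dur_s,
                                 tau_s = 14400)
  ser <- genConcentrationSeries(birchPulse(0, amp, 14400), ch,
                                duration_min = 1400, dt_s = 60)
  ce <- cumulativeEmission(ser, ch)
  expect_lt(abs(ce$co2_mgC - target) / target, 0.01)
})

test_that("suction maps to pore-throat diameter by the capillary law", {
  d <- poreThroatDiameter(c(1.5, 15, 50))
  # closed form 4 sigma / P evaluated independently
  expect_equal(d, 4 * 0.072 / (c(1.5, 15, 50) * 1000) * 1e6)
  expect_equal(nominalDiameter(d), c(200, 20, 6))
  expect_error(poreThroatDiameter(0), "positive")
  expect_error(poreThroatDiameter(-1.5), "positive")
  # strictly decreasing, homogeneous of degree -1
  s <- c(0.5, 1, 2, 10, 80)
  expect_true(all(diff(poreThroatDiameter(s)) < 0))
  expect_equal(poreThroatDiameter(2 * s), poreThroatDiameter(s) / 2)
})

test_that("imbibed water is a flagged mass difference", {
  expect_equal(imbibedWater(500, 530), 30)
  expect_equal(imbibedWater(500, 500), 0)
  expect_warning(w <- imbibedWater(500, 490), "negative")
  expect_equal(w, -10)
})

test_that("imbibition correlates with emission when coupling is planted", {
  set.seed(21)
  imb <- runif(16, 10, 60)
  co2 <- 3 * imb + rnorm(16, 0, 8)     # planted positive coupling
  r <- correlate(imb, co2)
  expect_gt(r$r, 0)
  expect_lt(r$p, 0.05)
})
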