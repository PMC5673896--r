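test_that("formula library honors counts, bounds and class regions", {
  lib1 <- genFormulaLibrary(1, seed = 7)
  expect_equal(nrow(lib1), 9)
  expect_setequal(lib1$class, classLabels())

  lib <- sharedLibrary()
  expect_true(all(table(lib$class) == 220))
  expect_true(all(lib$neutral_mass > 201 & lib$neutral_mass < 1199))
  expect_true(all(lib$dbe >= 0 & lib$dbe == round(lib$dbe)))
  expect_true(all(lib$C <= 70 & lib$H <= 140 & lib$O <= 40 &
                    lib$N <= 4 & lib$S <= 2 & lib$P <= 2))
  # round trip: re-classification recovers every planted label
  expect_equal(classifyFormulas(lib$oc, lib$hc), lib$class)
  # formulas are distinct within class
  expect_false(any(duplicated(lib[c("class", "formula")])))
})

test_that("library generation is deterministic under a fixed seed", {
  expect_identical(genFormulaLibrary(5, seed = 42),
                   genFormulaLibrary(5, seed = 42))
})

test_that("zero-noise peak lists sit exactly at [M-H]- positions", {
  g <- genPeakList(mixture = c(carbohydrates = 1), n_peaks = 25,
                   mass_error_ppm = 0, noise_frac = 0, seed = 3,
                   library = sharedLibrary())
  expect_equal(g$truth$mz, g$truth$neutral_mass - 1.00727646677,
               tolerance = 1e-12)
  expect_equal(nPeaks(g$peakList), 25)
  expect_equal(nrow(g$truth), 25)      # one truth record per peak
})

test_that("a pure-lipid mixture yields a pure-lipid profile downstream", {
  g <- genPeakList(mixture = c(lipids = 1), n_peaks = 50,
                   mass_error_ppm = 0, seed = 8,
                   library = sharedLibrary())
  a <- assignFormulas(filterSNR(g$peakList))
  p <- abundanceProfile(a)
  expect_equal(p$lipids, 1)
  expect_equal(p$richness, 50)
})

test_that("peak generator rejects bad mixtures and is seed-stable", {
  expect_error(genPeakList(mixture = c(lipids = 0), seed = 1,
                           library = sharedLibrary()), "empty support")
  expect_error(genPeakList(mixture = c(nonsense = 1), seed = 1,
                           library = sharedLibrary()), "unknown")
  g1 <- genPeakList(n_peaks = 40, noise_frac = 0.2, seed = 11,
                    library = sharedLibrary())
  g2 <- genPeakList(n_peaks = 40, noise_frac = 0.2, seed = 11,
                    library = sharedLibrary())
  expect_identical(peaks(g1$peakList), peaks(g2$peakList))
  expect_identical(g1$truth, g2$truth)
  # noise peaks are all at or below the S/N threshold
  noise <- setdiff(peaks(g1$peakList)$mz, g1$truth$mz)
  expect_true(all(peaks(g1$peakList)$snr[
    peaks(g1$peakList)$mz %in% noise] <= 7))
})

test_that("zero flux gives a constant concentration series", {
  ser <- genConcentrationSeries(function(t) rep(0, length(t)),
                                chamberSpec(), duration_min = 30,
                                dt_s = 30)
  expect_equal(diff(range(seriesData(ser)$co2)), 0)
})

test_that("noiseless series obey the inverted flux equation stepwise", {
  ch <- chamberSpec(V = 5000, M = 80)
  A <- birchPulse(1e-5, 2e-3, 3600)
  ser <- genConcentrationSeries(A, ch, duration_min = 60, dt_s = 20)
  d <- seriesData(ser)
  k <- 1e-6 * (ch@M / ch@V) * (ch@R * ch@T / ch@Pa)
  mid <- (A(d$time_s[-1]) + A(d$time_s[-nrow(d)])) / 2
  expect_equal(diff(d$co2) / diff(d$time_s), k * mid, tolerance = 1e-10)
})

test_that("cumulative emission grows with pulse amplitude", {
  ch <- chamberSpec()
  dur <- 200 * 60
  int1 <- birchPulseIntegral(0, 1e-3, 3600, dur)
  int2 <- birchPulseIntegral(0, 3e-3, 3600, dur)
  expect_gt(int2, int1)
  # and the generator respects the closed form
  ser <- genConcentrationSeries(birchPulse(0, 1e-3, 3600), ch,
                                duration_min = 200, dt_s = 15)
  d <- seriesData(ser)
  k <- 1e-6 * (ch@M / ch@V) * (ch@R * ch@T / ch@Pa)
  expect_equal((d$co2[nrow(d)] - d$co2[1]) / k, int1, tolerance = 1e-4)
})

test_that("amplitude calibration hits a prescribed carbon integral", {
  ch <- chamberSpec()
  amp <- calibrateBirchAmplitude(245.1 * 1000, ch@M, 84000,
                                 baseline = 0, tau_s = 14400)
  got <- birchPulseIntegral(0, amp, 14400, 84000) * ch@M * 12.011 / 1000
  expect_equal(got, 245.1, tolerance = 1e-10)
  expect_error(calibrateBirchAmplitude(10, 100, 84000, baseline = 1),
               "baseline")
})

test_that("the full synthetic experiment has the factorial arithmetic", {
  ex <- genExperiment(treatmentDesign(n_per_cell = 4), n_peaks = 20,
                      noise_frac = 0, dt_s = 600, seed = 2,
                      library = sharedLibrary())
  expect_equal(length(ex$peakLists), 96)   # 16 cores x 2 x 3
  expect_equal(length(ex$gasSeries), 32)   # 16 cores x 2 structures
  expect_equal(nrow(ex$truth$flux), 32)
  expect_setequal(unique(ex$design$suction_kPa), c(1.5, 15, 50))
  # paired design: every core appears intact and homogenized
  expect_true(all(table(ex$truth$flux$core_id) == 2))
})

test_that("experiment generation is byte-deterministic under a seed", {
  d <- treatmentDesign(n_per_cell = 1)
  ex1 <- genExperiment(d, n_peaks = 15, dt_s = 600, seed = 5,
                       library = sharedLibrary())
  ex2 <- genExperiment(d, n_peaks = 15, dt_s = 600, seed = 5,
                       library = sharedLibrary())
  expect_identical(lapply(ex1$peakLists, peaks),
                   lapply(ex2$peakLists, peaks))
  expect_identical(lapply(ex1$gasSeries, seriesData),
                   lapply(ex2$gasSeries, seriesData))
  expect_identical(ex1$truth, ex2$truth)
})

test_that("a missing flux preset cell is named in the error", {
  pres <- defaultFluxPresets()
  pres <- pres[!(pres$moisture == "drought" &
                   pres$structure == "homogenized" &
                   pres$wetting == "bottom_groundwater"), ]
  expect_error(
    genExperiment(treatmentDesign(n_per_cell = 1), fluxPresets = pres,
                  n_peaks = 10, dt_s = 600, seed = 1,
                  library = sharedLibrary()),
    "moisture=drought, wetting=bottom_groundwater, structure=homogenized")
})

test_that("drought mixtures shift chemistry in the planted direction", {
  for (su in c(1.5, 15, 50)) {
    f <- defaultClassMixture("field", su)
    d <- defaultClassMixture("drought", su)
    expect_equal(sum(f), 1, tolerance = 1e-9)
    expect_equal(sum(d), 1, tolerance = 1e-9)
    expect_lt(d[["lipids"]], f[["lipids"]])
    expect_gt(d[["tannins"]], f[["tannins"]])
  }
  # fine pores carry more lignin+tannin than coarse pores
  expect_gt(defaultClassMixture("field", 50)[["lignin"]],
            defaultClassMixture("field", 1.5)[["lignin"]])
})
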