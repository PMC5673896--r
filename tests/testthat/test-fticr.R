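test_that("peak-list IO round-trips values and flags malformed input", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("mz,intensity,snr", "255.23295,10,50", "301.1,5,20",
               "420.2,2,9"), f)
  pl <- readPeakList(f)
  expect_equal(nPeaks(pl), 3)
  expect_equal(peaks(pl)$mz[1], 255.23295)

  g <- genPeakList(mixture = c(lignin = 1), n_peaks = 15, seed = 4,
                   library = sharedLibrary())
  f2 <- withr::local_tempfile(fileext = ".csv")
  writePeakList(g$peakList, f2)
  back <- readPeakList(f2)
  expect_equal(peaks(back)$mz, peaks(g$peakList)$mz, tolerance = 1e-12)
  expect_equal(peaks(back)$snr, peaks(g$peakList)$snr, tolerance = 1e-6)

  f3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("mz,intensity", "255.1,1", "-5,2"), f3)
  expect_error(readPeakList(f3), "line\\(s\\) 3")
  f4 <- withr::local_tempfile(fileext = ".csv")
  file.create(f4)
  expect_error(readPeakList(f4), "empty")
})

test_that("S/N filter is strictly greater-than and order preserving", {
  pl <- PeakList(mz = c(210, 300, 400, 500),
                 intensity = c(1, 2, 3, 4),
                 snr = c(7, 7.01, 100, 6.99))
  kept <- filterSNR(pl, 7)
  expect_equal(peaks(kept)$mz, c(300, 400))   # 7.00 removed, 7.01 kept
  all100 <- PeakList(mz = c(210, 300), intensity = c(1, 1),
                     snr = c(100, 100))
  expect_equal(peaks(filterSNR(all100)), peaks(all100))
  # planted noise removal: exactly the sub-threshold peaks go
  g <- genPeakList(mixture = c(lipids = .5, tannins = .5), n_peaks = 100,
                   noise_frac = 0.2, seed = 9, library = sharedLibrary())
  filt <- filterSNR(g$peakList)
  expect_equal(nPeaks(filt), nrow(g$truth))
  expect_equal(peaks(filt)$mz, sort(g$truth$mz))
})

test_that("exact-mass arithmetic assigns the palmitate test ion", {
  pl <- PeakList(mz = 255.23295, intensity = 1, snr = 100)
  a <- assignFormulas(pl)
  expect_equal(nrow(a), 1)
  expect_equal(a$formula, "C16H32O2")
  expect_equal(a$neutral_mass, 256.24023, tolerance = 1e-5)
  expect_lt(abs(a$error_ppm), 1)
  expect_equal(a$dbe, 1)
})

test_that("peaks outside the 200-1200 window are not assigned", {
  pl <- PeakList(mz = c(150.05, 255.23295, 1250.7),
                 intensity = c(1, 1, 1), snr = c(99, 99, 99))
  a <- assignFormulas(pl)
  expect_equal(a$mz, 255.23295)
})

test_that("zero-error planted formulas are recovered exactly", {
  g <- genPeakList(mixture = c(lignin = .4, lipids = .3, unnamed = .3),
                   n_peaks = 60, mass_error_ppm = 0, seed = 5,
                   library = sharedLibrary())
  a <- assignFormulas(g$peakList)
  m <- merge(g$truth, a, by = "mz")
  expect_equal(nrow(m), nrow(g$truth))
  expect_gte(mean(m$formula.x == m$formula.y), 0.99)
})

test_that("assignment matches the brute-force oracle on a small sample", {
  g <- genPeakList(mixture = c(lignin = .5, proteins = .5), n_peaks = 15,
                   mass_error_ppm = 0.3, seed = 12,
                   library = sharedLibrary())
  a <- assignFormulas(g$peakList)
  for (i in seq_len(nPeaks(g$peakList))) {
    mz <- peaks(g$peakList)$mz[i]
    best <- oracleBest(mz)
    row <- a[abs(a$mz - mz) < 1e-9, ]
    if (is.null(best)) {
      expect_equal(nrow(row), 0)
    } else {
      expect_equal(nrow(row), 1)
      expect_equal(unlist(row[c("C", "H", "O", "N", "S", "P")]),
                   unlist(best[c("C", "H", "O", "N", "S", "P")]),
                   ignore_attr = TRUE)
    }
  }
})

test_that("compound classification honors boxes, precedence and bounds", {
  expect_equal(classifyFormulas(0.2, 1.8), "lipids")
  expect_equal(classifyFormulas(0.5, 1.0), "lignin")
  expect_equal(classifyFormulas(1.4, 0.9), "unnamed")
  # the documented lipid/unsaturated-HC overlap resolves to unsat HC
  expect_equal(classifyFormulas(0.1, 1.8), "unsaturated_hydrocarbons")
  expect_equal(classifyFormulas(0.125, 1.5), "unsaturated_hydrocarbons")
  # open/closed ends: H/C = 1.5 leaves lignin (open) and enters proteins
  expect_equal(classifyFormulas(0.5, 1.5), "proteins")
  expect_equal(classifyFormulas(0.5, 1.4999999), "lignin")
  # H/C = 2.5 exactly is outside the open unsat-HC top, inside lipids
  expect_equal(classifyFormulas(0.1, 2.5), "lipids")
  expect_equal(classifyFormulas(0.9, 0.1), "unnamed")
})

test_that("abundance profiles are count-normalized with unnamed included", {
  a10 <- data.frame(class = rep("lipids", 10))
  p <- abundanceProfile(a10, sampleId = "s")
  expect_equal(p$lipids, 1)
  expect_equal(p$richness, 10)
  a4 <- data.frame(class = c(rep("lignin", 3), "unnamed"))
  p4 <- abundanceProfile(a4)
  expect_equal(p4$lignin, 0.75)
  expect_equal(p4$unnamed, 0.25)
  labs <- classLabels()
  expect_equal(sum(unlist(p4[labs])), 1, tolerance = 1e-9)
  expect_error(abundanceProfile(data.frame()), "empty")
})

test_that("homologous-series detection finds CH2 chains", {
  base <- 300.1
  mz <- c(base, base + 14.0156500642, 450.3)
  pl <- PeakList(mz = mz, intensity = rep(1, 3), snr = rep(99, 3))
  ser <- detectHomologousSeries(pl)
  expect_equal(lengths(ser), 2)
  expect_equal(peaks(pl)$mz[ser[[1]]], mz[1:2])
})

test_that("internal calibration is ~identity on drift-free data", {
  g <- genPeakList(mixture = c(lignin = .5, lipids = .5), n_peaks = 150,
                   mass_error_ppm = 0, seed = 6,
                   library = sharedLibrary())
  cal <- calibrateInternal(g$peakList)
  expect_true(cal$report$calibrated)
  expect_lt(abs(cal$report$a_ppm), 0.05)
  expect_lt(abs(cal$report$b_ppm_per_da * 1000), 0.05)
})

test_that("internal calibration removes a planted 0.8 ppm drift", {
  g <- genPeakList(mixture = c(lignin = .5, lipids = .5), n_peaks = 150,
                   mass_error_ppm = 0.1, drift_ppm = c(0.8, 0),
                   seed = 6, library = sharedLibrary())
  cal <- calibrateInternal(g$peakList)
  expect_true(cal$report$calibrated)
  a <- assignFormulas(cal$peakList)
  expect_lt(median(abs(a$error_ppm)), 0.2)
})

test_that("calibration improves recovery under drift with a slope", {
  g <- genPeakList(mixture = c(lignin = .5, lipids = .5), n_peaks = 150,
                   mass_error_ppm = 0.1, drift_ppm = c(0.8, 5e-4),
                   seed = 7, library = sharedLibrary())
  recov <- function(pl) {
    a <- assignFormulas(pl)
    if (nrow(a) == 0) return(0)
    hits <- vapply(seq_len(nrow(g$truth)), function(i) {
      j <- which.min(abs(a$mz - g$truth$mz[i]))
      abs(a$mz[j] - g$truth$mz[i]) < 0.005 &&
        a$formula[j] == g$truth$formula[i]
    }, logical(1))
    mean(hits)
  }
  uncal <- recov(g$peakList)
  cal <- recov(calibrateInternal(g$peakList)$peakList)
  expect_gt(cal, uncal)
  expect_gte(cal, 0.8)   # residual isobaric collisions cap recovery
})

test_that("calibration on a chain-free list warns and returns input", {
  pl <- PeakList(mz = c(255.2329, 411.3, 587.25), intensity = rep(1, 3),
                 snr = rep(50, 3))
  expect_warning(res <- calibrateInternal(pl), "skipped")
  expect_false(res$report$calibrated)
  expect_equal(peaks(res$peakList), peaks(pl))
})
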