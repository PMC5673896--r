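#' Detect CH2 homologous series in a peak list
#'
#' Natural organic matter spectra contain long homologous series whose
#' members differ by exactly one CH2 unit (14.0156500642 Da). Series are
#' found by chaining peaks whose spacing matches the CH2 mass within a
#' relative tolerance.
#'
#' @param x a [PeakList-class].
#' @param tolPpm matching tolerance on the spacing, ppm of the member
#'   m/z (default 3).
#' @return List of integer vectors, each the peak indices (into
#'   `peaks(x)`) of one series of length >= 2, ordered by m/z.
#' @export
detectHomologousSeries <- function(x, tolPpm = 3) {
  stopifnot(is(x, "PeakList"))
  mz <- peaks(x)$mz
  n <- length(mz)
  nxt <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    target <- mz[i] + CH2_MASS
    tolDa <- tolPpm * 1e-6 * target
    j <- findInterval(target - tolDa, mz) + 1L
    while (j <= n && mz[j] <= target + tolDa) {
      if (is.na(nxt[i]) ||
          abs(mz[j] - target) < abs(mz[nxt[i]] - target))
        nxt[i] <- j
      j <- j + 1L
    }
  }
  hasPrev <- rep(FALSE, n)
  hasPrev[nxt[!is.na(nxt)]] <- TRUE
  series <- list()
  for (i in seq_len(n)) {
    if (hasPrev[i] || is.na(nxt[i])) next
    chain <- i
    while (!is.na(nxt[chain[length(chain)]]))
      chain <- c(chain, nxt[chain[length(chain)]])
    series[[length(series) + 1L]] <- chain
  }
  series
}

#' Internal mass calibration on organic-matter homologous series
#'
#' Implements the standard internal-calibration step for natural organic
#' matter: CH2-spaced homologous series are detected, their member peaks
#' are given provisional formula assignments at a relaxed tolerance, and
#' the resulting mass errors are regressed on m/z to fit a linear ppm
#' correction \eqn{ppm(m) = a + b m}. The correction is applied as
#' \eqn{m' = m / (1 + ppm(m) \times 10^{-6})}. A single
#' median-absolute-deviation trimming pass removes provisional
#' mis-assignments before the final fit.
#'
#' If fewer than `minAnchors` usable anchor peaks are found the input is
#' returned unchanged with `report$calibrated = FALSE` and a warning.
#'
#' @param x a [PeakList-class] (S/N filtering should already have been
#'   applied).
#' @param seriesTolPpm CH2 spacing tolerance for series detection, ppm.
#' @param minSeriesLength shortest series whose members become anchors.
#' @param anchorTolPpm provisional assignment tolerance for anchors, ppm.
#' @param minAnchors minimum assigned anchors required to fit.
#' @param bounds element bounds for the provisional assignments. The
#'   default restricts anchors to CHO-only compositions: homologous
#'   calibration series in natural organic matter are CHO families, and
#'   the sparser CHO space keeps provisional assignments essentially
#'   unambiguous even at the relaxed anchor tolerance.
#' @return List with `peakList` (corrected [PeakList-class]) and
#'   `report`: `calibrated` flag, intercept `a_ppm`, slope `b_ppm_per_da`,
#'   residual `rms_ppm`, `n_series` and `n_anchors`.
#' @examples
#' lib <- genFormulaLibrary(2, seed = 1)
#' pl <- genPeakList(n_peaks = 60, seed = 1, library = lib,
#'                   mass_error_ppm = 0, drift_ppm = c(0.8, 0))
#' calibrateInternal(pl)$report[c("calibrated", "a_ppm")]
#' @export
calibrateInternal <- function(x, seriesTolPpm = 3, minSeriesLength = 3,
                              anchorTolPpm = 3, minAnchors = 5,
                              bounds = elementBounds(maxN = 0, maxS = 0,
                                                     maxP = 0)) {
  stopifnot(is(x, "PeakList"))
  noCal <- function(nSeries, nAnchors) {
    warning("internal calibration skipped: not enough homologous-series ",
            "anchors")
    list(peakList = x,
         report = list(calibrated = FALSE, a_ppm = NA_real_,
                       b_ppm_per_da = NA_real_, rms_ppm = NA_real_,
                       n_series = nSeries, n_anchors = nAnchors))
  }
  series <- detectHomologousSeries(x, tolPpm = seriesTolPpm)
  series <- series[lengths(series) >= minSeriesLength]
  if (length(series) == 0) return(noCal(0L, 0L))
  anchorIdx <- sort(unique(unlist(series)))
  anchors <- peaks(x)[anchorIdx, , drop = FALSE]
  prov <- assignFormulas(anchors, tolerancePpm = anchorTolPpm,
                         bounds = bounds)
  if (nrow(prov) < minAnchors)
    return(noCal(length(series), nrow(prov)))
  fit <- lm(error_ppm ~ mz, data = prov)
  for (it in 1:3) {                     # MAD-trimmed refits
    res <- stats::residuals(fit)
    keep <- abs(res) <= 2.5 * stats::mad(res) + 1e-12
    if (sum(keep) < minAnchors) break
    fit <- lm(error_ppm ~ mz, data = prov[keep, , drop = FALSE])
  }
  a <- unname(coef(fit)[1]); b <- unname(coef(fit)[2])
  mz <- peaks(x)$mz
  mzCorr <- mz / (1 + (a + b * mz) * 1e-6)
  df <- peaks(x)
  df$mz <- mzCorr
  df <- df[order(df$mz), , drop = FALSE]
  rownames(df) <- NULL
  out <- new("PeakList", peaks = df, polarity = polarity(x),
             sampleId = sampleId(x))
  list(peakList = out,
       report = list(calibrated = TRUE, a_ppm = a, b_ppm_per_da = b,
                     rms_ppm = sqrt(mean(stats::residuals(fit)^2)),
                     n_series = length(series),
                     n_anchors = nrow(prov)))
}
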