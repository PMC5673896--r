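#' Generate a synthetic peak list with known formula truth
#'
#' Draws formulas from a class mixture, converts them to [M-H]- m/z with
#' Gaussian ppm mass error and an optional systematic linear drift, and
#' adds low-S/N noise peaks. Signal peaks get S/N > 7.5 so the standard
#' S/N > 7 filter keeps exactly the planted peaks; noise peaks get
#' S/N in [1, 7].
#'
#' Within each class, formulas are drawn without replacement from the
#' library, so every observed m/z has exactly one truth record.
#'
#' @param mixture named numeric vector of class weights over (a subset
#'   of) the nine labels of [classLabels()]; normalized to sum to one.
#' @param n_peaks total number of peaks (signal + noise).
#' @param mass_error_ppm standard deviation of the random ppm mass
#'   error (<= 1 for nominal instrument behaviour).
#' @param noise_frac fraction of `n_peaks` that are noise peaks, in
#'   [0, 1).
#' @param drift_ppm length-2 numeric `c(a, b)`: systematic miscalibration
#'   `ppm(m) = a + b*m` applied to the true m/z, removable by
#'   [calibrateInternal()].
#' @param seed integer RNG seed.
#' @param library formula library from [genFormulaLibrary()]; by default
#'   a 200-per-class library generated from `seed`.
#' @param sampleId sample identifier.
#' @return List with `peakList` (a [PeakList-class]) and `truth`, a
#'   data.frame with one row per signal peak: observed `mz`, `formula`,
#'   `class`, element counts and `neutral_mass`.
#' @examples
#' g <- genPeakList(mixture = c(lipids = 1), n_peaks = 20, seed = 3,
#'                  mass_error_ppm = 0)
#' all(classifyFormulas(g$truth$oc, g$truth$hc) == "lipids")
#' @export
genPeakList <- function(mixture = c(lignin = 0.4, lipids = 0.2,
                                    unnamed = 0.4),
                        n_peaks = 200, mass_error_ppm = 0.2,
                        noise_frac = 0, drift_ppm = c(0, 0), seed = 1,
                        library = NULL, sampleId = "synthetic") {
  stopifnot(noise_frac >= 0, noise_frac < 1, n_peaks >= 1,
            length(drift_ppm) == 2)
  mixture <- mixture[mixture > 0]
  if (length(mixture) == 0)
    stop("mixture has empty support")
  bad <- setdiff(names(mixture), classLabels())
  if (length(bad))
    stop("unknown mixture classes: ", paste(bad, collapse = ", "))
  mixture <- mixture / sum(mixture)
  if (is.null(library))
    library <- genFormulaLibrary(max(200, n_peaks), seed = seed)
  set.seed(seed)
  nNoise <- round(noise_frac * n_peaks)
  nSignal <- n_peaks - nNoise
  cls <- sample(names(mixture), nSignal, replace = TRUE, prob = mixture)
  counts <- table(cls)
  truthRows <- lapply(names(counts), function(cl) {
    pool <- library[library$class == cl, , drop = FALSE]
    k <- counts[[cl]]
    if (nrow(pool) < k)
      stop("library has only ", nrow(pool), " '", cl,
           "' formulas but ", k, " were requested; enlarge the library")
    pool[sample(nrow(pool), k), , drop = FALSE]
  })
  truth <- do.call(rbind, truthRows)
  mzTrue <- truth$neutral_mass - PROTON_MASS
  errPpm <- rnorm(nSignal, 0, mass_error_ppm) +
    drift_ppm[1] + drift_ppm[2] * mzTrue
  mzObs <- mzTrue * (1 + errPpm * 1e-6)
  snrSig <- 7.5 + rlnorm(nSignal, meanlog = log(60), sdlog = 1)
  sig <- data.frame(mz = mzObs, intensity = snrSig, snr = snrSig)
  truth$mz <- mzObs
  if (nNoise > 0) {
    noise <- data.frame(mz = runif(nNoise, 210, 1150),
                        snr = runif(nNoise, 1, 7))
    noise$intensity <- noise$snr
    sig <- rbind(sig, noise[, c("mz", "intensity", "snr")])
  }
  pl <- PeakList(mz = sig$mz, intensity = sig$intensity, snr = sig$snr,
                 sampleId = sampleId)
  truth <- truth[order(truth$mz), , drop = FALSE]
  rownames(truth) <- NULL
  list(peakList = pl,
       truth = truth[, c("mz", "formula", "class", "C", "H", "O", "N",
                         "S", "P", "neutral_mass", "oc", "hc", "dbe")])
}
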