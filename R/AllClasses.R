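#' PeakList: one sample's mass-spectral peaks
#'
#' Container for a single FT-ICR-MS sample: m/z, intensity and
#' signal-to-noise triples plus polarity and sample identity. Peaks are
#' stored sorted by m/z. Only negative-mode ([M-H]-) data are supported,
#' matching electrospray analysis of natural organic matter.
#'
#' @slot peaks data.frame with numeric columns `mz` (Da), `intensity`
#'   (arbitrary units) and `snr` (signal-to-noise ratio).
#' @slot polarity character, `"negative"`.
#' @slot sampleId character scalar identifying the sample.
#'
#' @seealso [PeakList()] constructor, [readPeakList()], [filterSNR()],
#'   [assignFormulas()]
#' @exportClass PeakList
setClass("PeakList",
  slots = c(peaks = "data.frame", polarity = "character",
            sampleId = "character"))

setValidity("PeakList", function(object) {
  p <- object@peaks
  msg <- character()
  need <- c("mz", "intensity", "snr")
  if (!all(need %in% names(p)))
    msg <- c(msg, sprintf("peaks must have columns %s",
                          paste(need, collapse = ", ")))
  else {
    if (nrow(p) && any(!is.finite(p$mz) | p$mz <= 0))
      msg <- c(msg, "mz must be finite and positive")
    if (nrow(p) > 1 && is.unsorted(p$mz, strictly = TRUE))
      msg <- c(msg, "mz must be strictly increasing")
    if (nrow(p) && any(p$snr < 0, na.rm = TRUE))
      msg <- c(msg, "snr must be >= 0")
  }
  if (length(object@polarity) != 1 || object@polarity != "negative")
    msg <- c(msg, "polarity must be \"negative\"")
  if (length(object@sampleId) != 1)
    msg <- c(msg, "sampleId must be a single string")
  if (length(msg)) msg else TRUE
})

#' Construct a PeakList
#'
#' Rows are sorted by m/z; exact duplicate m/z values are an error (a
#' centroided spectrum has one entry per peak).
#'
#' @param mz numeric vector of m/z values (Da).
#' @param intensity numeric vector of peak intensities.
#' @param snr numeric vector of signal-to-noise ratios; if `NULL`,
#'   estimated as `intensity / noiseFloor`.
#' @param sampleId sample identifier.
#' @param noiseFloor intensity corresponding to S/N = 1, used only when
#'   `snr` is missing.
#' @return A [PeakList-class] object.
#' @examples
#' pl <- PeakList(mz = c(255.233, 301.1), intensity = c(10, 5),
#'                snr = c(50, 20), sampleId = "s1")
#' nPeaks(pl)
#' @export
PeakList <- function(mz, intensity, snr = NULL, sampleId = "sample",
                     noiseFloor = 1) {
  if (is.null(snr)) snr <- intensity / noiseFloor
  df <- data.frame(mz = as.numeric(mz), intensity = as.numeric(intensity),
                   snr = as.numeric(snr))
  df <- df[order(df$mz), , drop = FALSE]
  rownames(df) <- NULL
  if (anyDuplicated(df$mz))
    stop("duplicate m/z values in peak list")
  new("PeakList", peaks = df, polarity = "negative",
      sampleId = as.character(sampleId))
}

#' ClassScheme: Van Krevelen compound-class boxes
#'
#' Eight rectangular regions in (O/C, H/C) space mapping a molecular
#' formula to a biomolecule-like compound class, plus a precedence order
#' used to resolve the documented overlap between the lipid and
#' unsaturated-hydrocarbon boxes. Formulas falling in no box are
#' "unnamed" (they still count toward richness and the relative-abundance
#' denominator).
#'
#' @slot boxes data.frame with columns `class`, `oc_lo`, `oc_lo_closed`,
#'   `oc_hi`, `oc_hi_closed`, `hc_lo`, `hc_lo_closed`, `hc_hi`,
#'   `hc_hi_closed`. Closed flags indicate whether the bound itself is
#'   inside the box.
#' @slot precedence character vector of class names; the first box (in
#'   this order) containing a point wins.
#' @seealso [vanKrevelenScheme()], [classifyFormulas()]
#' @exportClass ClassScheme
setClass("ClassScheme",
  slots = c(boxes = "data.frame", precedence = "character"))

setValidity("ClassScheme", function(object) {
  b <- object@boxes
  msg <- character()
  need <- c("class", "oc_lo", "oc_lo_closed", "oc_hi", "oc_hi_closed",
            "hc_lo", "hc_lo_closed", "hc_hi", "hc_hi_closed")
  if (!all(need %in% names(b)))
    msg <- c(msg, "boxes is missing required columns")
  else {
    if (!setequal(object@precedence, b$class))
      msg <- c(msg, "precedence must be a permutation of box class names")
    if (any(b$oc_lo > b$oc_hi) || any(b$hc_lo > b$hc_hi))
      msg <- c(msg, "degenerate box: lower bound exceeds upper bound")
  }
  if (length(msg)) msg else TRUE
})

#' ChamberSpec: physical constants of a closed flux chamber
#'
#' Parameters entering the ideal-gas flux equation
#' \eqn{A = (dC/dt)(V/M)(Pa/(RT))}: headspace volume, dry soil mass,
#' pressure, temperature and the gas constant in matching units.
#'
#' @slot V total chamber volume, cm3.
#' @slot M dry soil mass, g.
#' @slot Pa atmospheric pressure, kPa.
#' @slot T air temperature, K.
#' @slot R gas constant, cm3 kPa mol-1 K-1 (8.3e3 by default).
#' @seealso [chamberSpec()], [fluxEq1()]
#' @exportClass ChamberSpec
setClass("ChamberSpec",
  slots = c(V = "numeric", M = "numeric", Pa = "numeric",
            T = "numeric", R = "numeric"))

setValidity("ChamberSpec", function(object) {
  vals <- c(V = object@V, M = object@M, Pa = object@Pa,
            T = object@T, R = object@R)
  if (length(vals) != 5 || any(!is.finite(vals)) || any(vals <= 0))
    "V, M, Pa, T and R must all be single, strictly positive numbers"
  else TRUE
})

#' Construct a ChamberSpec
#'
#' @param V chamber volume, cm3.
#' @param M dry soil mass, g.
#' @param Pa atmospheric pressure, kPa.
#' @param T air temperature, K.
#' @param R gas constant, cm3 kPa mol-1 K-1.
#' @return A [ChamberSpec-class] object.
#' @examples
#' chamberSpec(V = 2e4, M = 100)
#' @export
chamberSpec <- function(V = 2e4, M = 100, Pa = 101.325, T = 295.15,
                        R = GAS_CONSTANT_CM3) {
  new("ChamberSpec", V = V, M = M, Pa = Pa, T = T, R = R)
}

#' HeadspaceSeries: chamber gas concentration time series
#'
#' CO2 and CH4 mole fractions against time for one core's rewetting run,
#' with a phase marker separating active rewetting from the post-wetting
#' incubation.
#'
#' @slot data data.frame with columns `time_s`, `co2` and `ch4`
#'   (mole fraction, dimensionless).
#' @slot coreId core identifier.
#' @slot rewetEnd_s end of the rewetting phase, seconds (post-wetting
#'   incubation runs from here to the end of the series).
#' @seealso [headspaceSeries()], [genConcentrationSeries()], [fluxSeries()]
#' @exportClass HeadspaceSeries
setClass("HeadspaceSeries",
  slots = c(data = "data.frame", coreId = "character",
            rewetEnd_s = "numeric"))

setValidity("HeadspaceSeries", function(object) {
  d <- object@data
  msg <- character()
  if (!all(c("time_s", "co2", "ch4") %in% names(d)))
    msg <- c(msg, "data must have columns time_s, co2, ch4")
  else {
    if (nrow(d) > 1 && is.unsorted(d$time_s, strictly = TRUE))
      msg <- c(msg, "time_s must be strictly increasing")
    if (nrow(d) && any(c(d$co2, d$ch4) < 0, na.rm = TRUE))
      msg <- c(msg, "concentrations must be >= 0")
  }
  if (length(object@rewetEnd_s) != 1 || object@rewetEnd_s < 0)
    msg <- c(msg, "rewetEnd_s must be a single nonnegative number")
  if (length(msg)) msg else TRUE
})

#' Construct a HeadspaceSeries
#'
#' @param time_s time, seconds, strictly increasing.
#' @param co2,ch4 mole fractions (dimensionless; 400 ppm = 4e-4).
#' @param coreId core identifier.
#' @param rewetEnd_s end of the rewetting phase, seconds.
#' @return A [HeadspaceSeries-class] object.
#' @export
headspaceSeries <- function(time_s, co2, ch4 = rep(0, length(time_s)),
                            coreId = "core", rewetEnd_s = 200 * 60) {
  new("HeadspaceSeries",
      data = data.frame(time_s = as.numeric(time_s), co2 = as.numeric(co2),
                        ch4 = as.numeric(ch4)),
      coreId = as.character(coreId), rewetEnd_s = rewetEnd_s)
}
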