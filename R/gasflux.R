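#' Least-squares slope of concentration against time
#'
#' Ordinary least-squares slope of a gas mole fraction over a time
#' window; the elementary quantity entering the chamber flux equation.
#'
#' @param series a [HeadspaceSeries-class].
#' @param window length-2 numeric, time span in seconds (closed
#'   interval); default the whole series.
#' @param gas `"co2"` or `"ch4"`.
#' @return List with `slope` (mole fraction s-1), `se`, `n` and
#'   `window`.
#' @export
estimateSlope <- function(series, window = NULL, gas = c("co2", "ch4")) {
  gas <- match.arg(gas)
  d <- seriesData(series)
  if (is.null(window)) window <- range(d$time_s)
  d <- d[d$time_s >= window[1] & d$time_s <= window[2], , drop = FALSE]
  if (nrow(d) < 3)
    stop("need at least 3 points in the window")
  if (diff(range(d$time_s)) == 0)
    stop("degenerate window: zero time variance")
  fit <- lm(d[[gas]] ~ d$time_s)
  res <- stats::residuals(fit)
  n <- nrow(d)
  sxx <- sum((d$time_s - mean(d$time_s))^2)
  list(slope = unname(coef(fit)[2]),
       se = sqrt(sum(res^2) / (n - 2) / sxx),
       n = n, window = window)
}

#' Chamber flux from a concentration slope
#'
#' Applies the ideal-gas chamber equation
#' \eqn{A = (dC/dt)(V/M)(Pa/(RT))}, with a single factor of 1e6
#' converting mol g-1 s-1 to umol g-1 s-1. The sign of the slope is
#' preserved, so uptake yields a negative flux.
#'
#' @param slope concentration slope, mole fraction s-1 (vectorized).
#' @param chamber a [ChamberSpec-class].
#' @return Flux in umol (g soil)-1 s-1.
#' @examples
#' fluxEq1(1e-9, chamberSpec(V = 1000, M = 100))
#' @export
fluxEq1 <- function(slope, chamber) {
  validObject(chamber)
  slope * (chamber@V / chamber@M) *
    (chamber@Pa / (chamber@R * chamber@T)) * 1e6
}

#' Flux time series from contiguous slope windows
#'
#' Splits the series into contiguous windows (a finer width during the
#' rewetting phase, a coarser one afterwards), estimates the OLS slope
#' in each, and converts slopes to fluxes. Each flux is reported at the
#' window midpoint.
#'
#' @param series a [HeadspaceSeries-class].
#' @param chamber a [ChamberSpec-class].
#' @param gas `"co2"` or `"ch4"`.
#' @param rewetWindow_s slope window width during rewetting, s
#'   (default 5 min).
#' @param postWindow_s slope window width post-wetting, s
#'   (default 30 min).
#' @return data.frame with `time_s` (window midpoint), `slope`, `flux`
#'   (umol g-1 s-1), `n` and `phase`.
#' @export
fluxSeries <- function(series, chamber, gas = c("co2", "ch4"),
                       rewetWindow_s = 300, postWindow_s = 1800) {
  gas <- match.arg(gas)
  d <- seriesData(series)
  tEnd <- max(d$time_s)
  rewetEnd <- min(rewetEnd(series), tEnd)
  edges <- unique(c(seq(min(d$time_s), rewetEnd, by = rewetWindow_s),
                    rewetEnd,
                    if (tEnd > rewetEnd)
                      c(seq(rewetEnd, tEnd, by = postWindow_s), tEnd)))
  edges <- sort(unique(edges))
  rows <- list()
  for (i in seq_len(length(edges) - 1)) {
    w <- c(edges[i], edges[i + 1])
    sub <- d[d$time_s >= w[1] & d$time_s <= w[2], , drop = FALSE]
    if (nrow(sub) < 3 || diff(range(sub$time_s)) == 0) next
    sl <- estimateSlope(series, window = w, gas = gas)
    rows[[length(rows) + 1]] <- data.frame(
      time_s = mean(w), slope = sl$slope,
      flux = fluxEq1(sl$slope, chamber), n = sl$n,
      phase = if (w[2] <= rewetEnd) "rewetting" else "post_wetting")
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Trapezoidal cumulative carbon emission from a flux series
#'
#' Integrates a (possibly signed) flux series by the trapezoid rule and
#' converts to mass of carbon:
#' \eqn{\int A\,dt \times M \times 12.011} ug C per core.
#'
#' @param time_s times, s.
#' @param flux fluxes, umol g-1 s-1.
#' @param chamber a [ChamberSpec-class] (supplies the soil mass M).
#' @param span optional length-2 numeric restricting integration.
#' @return Cumulative emission, ug C per core.
#' @examples
#' # constant 1e-6 umol/g/s for 1000 s over 100 g: 0.1 umol = 1.2011 ug C
#' integrateCumulative(c(0, 1000), c(1e-6, 1e-6), chamberSpec(M = 100))
#' @export
integrateCumulative <- function(time_s, flux, chamber, span = NULL) {
  validObject(chamber)
  if (!is.null(span)) {
    keep <- time_s >= span[1] & time_s <= span[2]
    time_s <- time_s[keep]; flux <- flux[keep]
  }
  if (length(time_s) < 2)
    stop("empty or degenerate integration span")
  n <- length(time_s)
  integral <- sum(diff(time_s) * (flux[-1] + flux[-n]) / 2)
  integral * chamber@M * CARBON_ATOMIC_MASS
}

#' Cumulative CO2-C and CH4-C for one core
#'
#' Full chain for one headspace series: windowed slopes, fluxes, and
#' trapezoidal integration over rewetting plus post-wetting. The flux at
#' the series endpoints is taken from the first/last window so the
#' integral covers the complete span. CO2-C is reported in mg and CH4-C
#' in ug, the conventional magnitudes for the two gases.
#'
#' @inheritParams fluxSeries
#' @return List with `co2_mgC`, `ch4_ugC` and the integration `span_s`.
#' @export
cumulativeEmission <- function(series, chamber, rewetWindow_s = 300,
                               postWindow_s = 1800) {
  d <- seriesData(series)
  span <- range(d$time_s)
  one <- function(gas) {
    fs <- fluxSeries(series, chamber, gas = gas,
                     rewetWindow_s = rewetWindow_s,
                     postWindow_s = postWindow_s)
    tt <- c(span[1], fs$time_s, span[2])
    ff <- c(fs$flux[1], fs$flux, fs$flux[nrow(fs)])
    integrateCumulative(tt, ff, chamber)
  }
  list(co2_mgC = one("co2") / 1000, ch4_ugC = one("ch4"),
       span_s = span)
}

#' Pore-throat diameter from extraction suction
#'
#' Capillary (Young-Laplace/Kelvin) mapping from the magnitude of the
#' applied suction to the largest water-filled pore-throat diameter:
#' \eqn{d = 4\sigma\cos\theta / P}, returned in micrometres. At the
#' standard surface tension of water (0.072 N m-1) and zero contact
#' angle, suctions of 1.5, 15 and 50 kPa correspond to 192, 19.2 and
#' 5.76 um — nominally ~200, 20 and 6 um pore throats.
#'
#' @param suction_kPa magnitude of the applied suction, kPa (> 0).
#' @param surfaceTension water surface tension, N m-1.
#' @param contactAngle contact angle, radians.
#' @return Diameter in um (vectorized over `suction_kPa`).
#' @examples
#' poreThroatDiameter(c(1.5, 15, 50))
#' nominalDiameter(poreThroatDiameter(c(1.5, 15, 50)))  # 200 20 6
#' @export
poreThroatDiameter <- function(suction_kPa, surfaceTension = 0.072,
                               contactAngle = 0) {
  if (any(suction_kPa <= 0))
    stop("suction must be strictly positive")
  d_m <- 4 * surfaceTension * cos(contactAngle) / (suction_kPa * 1000)
  d_m * 1e6
}

#' One-significant-figure nominal pore size
#'
#' @param d_um diameter(s) in um.
#' @return `signif(d_um, 1)`.
#' @export
nominalDiameter <- function(d_um) signif(d_um, 1)

#' Water imbibed by a core during rewetting
#'
#' Difference of the core weights after and before rewetting. Negative
#' values (weight loss) are allowed but flagged with a warning.
#'
#' @param mass_pre,mass_post core masses, g (>= 0).
#' @return Grams of water imbibed.
#' @export
imbibedWater <- function(mass_pre, mass_post) {
  stopifnot(all(mass_pre >= 0), all(mass_post >= 0))
  w <- mass_post - mass_pre
  if (any(w < 0))
    warning("negative imbibition: core(s) lost weight during rewetting")
  w
}
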