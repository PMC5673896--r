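#' Birch-pulse flux profile
#'
#' The rewetting respiration pulse is modelled as a baseline plus a
#' single exponential decay, the simplest shape matching observed
#' dry-soil rewetting dynamics:
#' \eqn{A(t) = baseline + amplitude \; e^{-t/\tau}}.
#'
#' @param baseline steady flux, umol (g soil)-1 s-1.
#' @param amplitude pulse height above baseline at t = 0, umol g-1 s-1.
#' @param tau_s decay time constant, seconds.
#' @return A function of time (s) returning flux in umol g-1 s-1.
#' @examples
#' A <- birchPulse(1e-4, 1e-2, 14400)
#' A(c(0, 14400))
#' @export
birchPulse <- function(baseline, amplitude, tau_s) {
  force(baseline); force(amplitude); force(tau_s)
  function(t) baseline + amplitude * exp(-t / tau_s)
}

#' Closed-form time integral of a Birch pulse
#'
#' @param baseline,amplitude,tau_s pulse parameters (see [birchPulse()]).
#' @param duration_s integration span `[0, duration_s]`.
#' @return Integral in umol g-1.
#' @export
birchPulseIntegral <- function(baseline, amplitude, tau_s, duration_s) {
  baseline * duration_s + amplitude * tau_s * (1 - exp(-duration_s / tau_s))
}

#' Calibrate a Birch-pulse amplitude to a target cumulative emission
#'
#' Solves for the amplitude such that the cumulative carbon emission
#' over `[0, duration_s]`, \eqn{\int A \, dt \times M \times 12.011},
#' equals a prescribed mass of carbon. Used to pin generator presets to
#' published treatment means.
#'
#' @param target_ugC target cumulative emission, ug C per core (use
#'   1000 x mg for CO2-C targets quoted in mg).
#' @param M dry soil mass, g.
#' @param duration_s emission window, s.
#' @param baseline baseline flux, umol g-1 s-1.
#' @param tau_s pulse decay constant, s.
#' @return Amplitude in umol g-1 s-1.
#' @export
calibrateBirchAmplitude <- function(target_ugC, M, duration_s,
                                    baseline = 0, tau_s = 14400) {
  totalUmolPerG <- target_ugC / CARBON_ATOMIC_MASS / M
  amp <- (totalUmolPerG - baseline * duration_s) /
    (tau_s * (1 - exp(-duration_s / tau_s)))
  if (amp < 0)
    stop("baseline alone exceeds the target emission; lower the baseline")
  amp
}

#' Generate a headspace concentration series from a flux profile
#'
#' Inverts the chamber flux equation: given A(t) in umol g-1 s-1, the
#' concentration obeys
#' \eqn{dC/dt = A \times 10^{-6} (M/V)(RT/Pa)} (mole fraction s-1). The
#' noiseless series is the cumulative trapezoidal integral of that rate
#' on the sampling grid, so a slope-based flux analysis recovers A(t)
#' exactly up to discretization.
#'
#' @param fluxProfile function of time (s) giving CO2 flux,
#'   umol g-1 s-1 (e.g. [birchPulse()]).
#' @param chamber a [ChamberSpec-class].
#' @param duration_min series length, minutes; the default covers the
#'   200-min rewetting phase plus a 20-h post-wetting incubation.
#' @param dt_s sampling interval, seconds.
#' @param noise_sd Gaussian noise on mole fractions.
#' @param seed RNG seed (only used when `noise_sd > 0`).
#' @param ch4Profile optional CH4 flux profile, same units; zero flux if
#'   `NULL`.
#' @param c0_co2,c0_ch4 initial mole fractions (ambient 400 ppm CO2,
#'   1.9 ppm CH4).
#' @param rewetEnd_min end of rewetting phase, minutes.
#' @param coreId core identifier.
#' @return A [HeadspaceSeries-class].
#' @examples
#' ser <- genConcentrationSeries(birchPulse(0, 1e-3, 3600),
#'                               chamberSpec(), duration_min = 60)
#' @export
genConcentrationSeries <- function(fluxProfile, chamber = chamberSpec(),
                                   duration_min = 1400, dt_s = 30,
                                   noise_sd = 0, seed = NULL,
                                   ch4Profile = NULL,
                                   c0_co2 = 400e-6, c0_ch4 = 1.9e-6,
                                   rewetEnd_min = 200, coreId = "core") {
  validObject(chamber)
  t <- seq(0, duration_min * 60, by = dt_s)
  k <- 1e-6 * (chamber@M / chamber@V) * (chamber@R * chamber@T / chamber@Pa)
  integ <- function(profile, c0) {
    rate <- k * profile(t)
    dC <- diff(t) * (rate[-1] + rate[-length(rate)]) / 2
    c0 + c(0, cumsum(dC))
  }
  co2 <- integ(fluxProfile, c0_co2)
  ch4 <- if (is.null(ch4Profile)) rep(c0_ch4, length(t))
         else integ(ch4Profile, c0_ch4)
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    co2 <- pmax(0, co2 + rnorm(length(t), 0, noise_sd))
    ch4 <- pmax(0, ch4 + rnorm(length(t), 0, noise_sd))
  }
  headspaceSeries(time_s = t, co2 = co2, ch4 = ch4, coreId = coreId,
                  rewetEnd_s = rewetEnd_min * 60)
}
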