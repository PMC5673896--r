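#' Full-factorial treatment design for a rewetting experiment
#'
#' Cores are assigned to the four antecedent-moisture x
#' wetting-direction cells (`n_per_cell` each; 4 by default, giving the
#' standard 16-core layout). Each core is measured intact and then again
#' after homogenization, with the core id stable across structure
#' levels (paired design), and pore water is drawn at three suctions.
#'
#' @param n_per_cell replicate cores per moisture x wetting cell.
#' @param suctions_kPa suction magnitudes, kPa.
#' @return data.frame with one row per core: `core_id`, `moisture`
#'   (`field`/`drought`), `wetting`
#'   (`top_precipitation`/`bottom_groundwater`), and attributes
#'   `structures` and `suctions_kPa` describing the within-core levels.
#' @examples
#' d <- treatmentDesign()
#' nrow(d)  # 16 cores
#' @export
treatmentDesign <- function(n_per_cell = 4,
                            suctions_kPa = c(1.5, 15, 50)) {
  stopifnot(n_per_cell >= 1)
  cells <- expand.grid(moisture = c("field", "drought"),
                       wetting = c("top_precipitation",
                                   "bottom_groundwater"),
                       rep = seq_len(n_per_cell),
                       KEEP.OUT.ATTRS = FALSE,
                       stringsAsFactors = FALSE)
  cells <- cells[order(cells$moisture, cells$wetting, cells$rep), ]
  cells$core_id <- sprintf("C%02d", seq_len(nrow(cells)))
  out <- cells[, c("core_id", "moisture", "wetting")]
  rownames(out) <- NULL
  attr(out, "structures") <- c("intact", "homogenized")
  attr(out, "suctions_kPa") <- suctions_kPa
  out
}

#' Published-mean cumulative-emission presets per treatment cell
#'
#' Target mean cumulative CO2-C (mg) and CH4-C (ug) per
#' moisture x wetting x structure cell, to which the generator's Birch
#' pulses are calibrated. Defaults are the intact/homogenized treatment
#' means of the laboratory experiment the package emulates (e.g. intact
#' drought + precipitation 245.1 mg CO2-C).
#'
#' @return data.frame with columns `moisture`, `wetting`, `structure`,
#'   `co2_mgC`, `ch4_ugC`.
#' @export
defaultFluxPresets <- function() {
  cells <- expand.grid(moisture = c("field", "drought"),
                       wetting = c("top_precipitation",
                                   "bottom_groundwater"),
                       structure = c("intact", "homogenized"),
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  key <- paste(cells$moisture, cells$wetting, cells$structure)
  co2 <- c("field top_precipitation intact" = 51.7,
           "drought top_precipitation intact" = 245.1,
           "field bottom_groundwater intact" = 100.2,
           "drought bottom_groundwater intact" = 161.2,
           "field top_precipitation homogenized" = 108.6,
           "drought top_precipitation homogenized" = 208.6,
           "field bottom_groundwater homogenized" = 118.7,
           "drought bottom_groundwater homogenized" = 202.0)
  ch4 <- c("field top_precipitation intact" = 0.0536,
           "drought top_precipitation intact" = 0.0288,
           "field bottom_groundwater intact" = 0.0117,
           "drought bottom_groundwater intact" = 0.1032,
           "field top_precipitation homogenized" = 0.0785,
           "drought top_precipitation homogenized" = 0.0546,
           "field bottom_groundwater homogenized" = 0.0551,
           "drought bottom_groundwater homogenized" = 0.0418)
  cells$co2_mgC <- unname(co2[key])
  cells$ch4_ugC <- unname(ch4[key])
  cells
}

#' Default compound-class mixtures per pore-water fraction
#'
#' Encodes the qualitative pore-scale chemistry the experiment reports:
#' tightly held water from fine pore throats (50 kPa suction) is
#' enriched in lignin and tannins; loosely held water from coarse pores
#' (1.5 kPa) carries relatively more lipid-like, unsaturated-hydrocarbon
#' and unnamed signal. Antecedent drought depletes lipids and enriches
#' lignin and tannins. The magnitudes are free generator parameters (the
#' source experiment reports directions and significance, not effect
#' sizes); weights are renormalized to sum to one.
#'
#' @param moisture `"field"` or `"drought"`.
#' @param suction_kPa 1.5, 15 or 50.
#' @return Named numeric mixture over the nine class labels, summing
#'   to 1.
#' @export
defaultClassMixture <- function(moisture = c("field", "drought"),
                                suction_kPa = 1.5) {
  moisture <- match.arg(moisture)
  base <- switch(as.character(suction_kPa),
    "1.5" = c(lipids = 0.13, unsaturated_hydrocarbons = 0.06,
              proteins = 0.08, amino_sugars = 0.03, carbohydrates = 0.07,
              lignin = 0.28, tannins = 0.05,
              condensed_hydrocarbons = 0.04, unnamed = 0.26),
    "15"  = c(lipids = 0.10, unsaturated_hydrocarbons = 0.04,
              proteins = 0.08, amino_sugars = 0.03, carbohydrates = 0.08,
              lignin = 0.33, tannins = 0.07,
              condensed_hydrocarbons = 0.05, unnamed = 0.22),
    "50"  = c(lipids = 0.07, unsaturated_hydrocarbons = 0.02,
              proteins = 0.07, amino_sugars = 0.03, carbohydrates = 0.08,
              lignin = 0.38, tannins = 0.10,
              condensed_hydrocarbons = 0.05, unnamed = 0.20),
    stop("no default mixture for suction ", suction_kPa, " kPa"))
  if (moisture == "drought") {
    base["lipids"] <- base["lipids"] * 0.6
    base["lignin"] <- base["lignin"] * 1.15
    base["tannins"] <- base["tannins"] * 1.3
  }
  base / sum(base)
}

#' Generate a complete synthetic rewetting experiment
#'
#' Emits, with known ground truth, everything the analysis consumes:
#' one headspace series per core x structure (Birch pulses calibrated to
#' the flux presets, with lognormal between-core variation) and one peak
#' list per core x structure x suction (class mixtures from
#' [defaultClassMixture()], richness modulated by drought,
#' homogenization and wetting direction). Deterministic under a fixed
#' seed; every design cell must have a flux preset or the offending cell
#' is named in an error.
#'
#' @param design core table from [treatmentDesign()].
#' @param fluxPresets cell means from [defaultFluxPresets()].
#' @param n_peaks baseline signal+noise peaks per sample.
#' @param noise_frac fraction of sub-threshold noise peaks.
#' @param mass_error_ppm random ppm mass error SD.
#' @param drift_ppm systematic drift `c(a, b)` passed to [genPeakList()].
#' @param fluxCV lognormal coefficient of variation of core-level
#'   cumulative emissions around the cell mean.
#' @param chamber a [ChamberSpec-class].
#' @param dt_s gas sampling interval, s.
#' @param duration_min gas series length, min.
#' @param tau_s Birch-pulse decay constant, s.
#' @param library optional formula library (generated from `seed` if
#'   `NULL`).
#' @param seed integer RNG seed.
#' @return List with `design` (expanded sample table), `peakLists`
#'   (named list of [PeakList-class]), `gasSeries` (named list of
#'   [HeadspaceSeries-class]), `truth` (list: `formulas` per sample,
#'   `flux` per series with the planted cumulative targets), `chamber`
#'   and `library`.
#' @examples
#' \donttest{
#' ex <- genExperiment(treatmentDesign(n_per_cell = 1), n_peaks = 50,
#'                     seed = 2)
#' length(ex$peakLists)  # 4 cores x 2 structures x 3 suctions = 24
#' }
#' @export
genExperiment <- function(design = treatmentDesign(),
                          fluxPresets = defaultFluxPresets(),
                          n_peaks = 300, noise_frac = 0.1,
                          mass_error_ppm = 0.2, drift_ppm = c(0, 0),
                          fluxCV = 0.2, chamber = chamberSpec(),
                          dt_s = 60, duration_min = 1400,
                          tau_s = 14400, library = NULL, seed = 1) {
  set.seed(seed)
  structures <- attr(design, "structures")
  suctions <- attr(design, "suctions_kPa")
  if (is.null(structures)) structures <- c("intact", "homogenized")
  if (is.null(suctions)) suctions <- c(1.5, 15, 50)
  if (is.null(library))
    library <- genFormulaLibrary(max(300, n_peaks), seed = seed)
  duration_s <- duration_min * 60
  peakLists <- list(); gasSeries <- list()
  truthFormulas <- list(); truthFlux <- list()
  sampleRows <- list()
  for (i in seq_len(nrow(design))) {
    core <- design$core_id[i]
    moisture <- design$moisture[i]
    wetting <- design$wetting[i]
    for (st in structures) {
      preset <- fluxPresets[fluxPresets$moisture == moisture &
                            fluxPresets$wetting == wetting &
                            fluxPresets$structure == st, , drop = FALSE]
      if (nrow(preset) != 1)
        stop("missing flux preset for cell: moisture=", moisture,
             ", wetting=", wetting, ", structure=", st)
      gid <- paste(core, st, sep = "_")
      sdlog <- sqrt(log(1 + fluxCV^2))
      fac <- rlnorm(1, meanlog = -sdlog^2 / 2, sdlog = sdlog)
      co2Target_ugC <- preset$co2_mgC * 1000 * fac
      ch4Target_ugC <- preset$ch4_ugC * fac
      ampCo2 <- calibrateBirchAmplitude(co2Target_ugC, chamber@M,
                                        duration_s, baseline = 0,
                                        tau_s = tau_s)
      ampCh4 <- calibrateBirchAmplitude(ch4Target_ugC, chamber@M,
                                        duration_s, baseline = 0,
                                        tau_s = tau_s)
      gasSeries[[gid]] <- genConcentrationSeries(
        birchPulse(0, ampCo2, tau_s), chamber,
        duration_min = duration_min, dt_s = dt_s,
        ch4Profile = birchPulse(0, ampCh4, tau_s), coreId = gid)
      truthFlux[[gid]] <- data.frame(
        series_id = gid, core_id = core, moisture = moisture,
        wetting = wetting, structure = st,
        co2_mgC = co2Target_ugC / 1000, ch4_ugC = ch4Target_ugC,
        amp_co2 = ampCo2, amp_ch4 = ampCh4, tau_s = tau_s)
      for (su in suctions) {
        sid <- sprintf("%s_%s_%gkPa", core, st, su)
        mixture <- defaultClassMixture(moisture, su)
        nS <- round(n_peaks *
                      (1 + 0.10 * (moisture == "drought")) *
                      (1 + 0.10 * (st == "homogenized")) *
                      (1 + 0.05 * (wetting == "bottom_groundwater")))
        g <- genPeakList(mixture = mixture, n_peaks = nS,
                         mass_error_ppm = mass_error_ppm,
                         noise_frac = noise_frac, drift_ppm = drift_ppm,
                         seed = sample.int(.Machine$integer.max, 1),
                         library = library, sampleId = sid)
        peakLists[[sid]] <- g$peakList
        truthFormulas[[sid]] <- g$truth
        sampleRows[[sid]] <- data.frame(
          sample_id = sid, core_id = core, moisture = moisture,
          wetting = wetting, structure = st, suction_kPa = su,
          mixture_id = paste(moisture, su, sep = "_"))
      }
    }
  }
  list(design = do.call(rbind, c(sampleRows, list(make.row.names = FALSE))),
       coreTable = design,
       peakLists = peakLists, gasSeries = gasSeries,
       truth = list(formulas = truthFormulas,
                    flux = do.call(rbind,
                                   c(truthFlux,
                                     list(make.row.names = FALSE)))),
       chamber = chamber, library = library,
       params = list(n_peaks = n_peaks, noise_frac = noise_frac,
                     mass_error_ppm = mass_error_ppm,
                     drift_ppm = drift_ppm, fluxCV = fluxCV,
                     tau_s = tau_s, seed = seed))
}
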