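#' Default run configuration
#'
#' A fully serializable list of every parameter affecting a
#' generate-and-analyze run: seed, design shape, peak-generation
#' settings, processing tolerances, class-scheme precedence, flux
#' windows and transformation choices. [readRunConfig()] rejects keys
#' not present here.
#'
#' @param seed integer seed.
#' @return Nested named list.
#' @export
defaultRunConfig <- function(seed = 1) {
  list(
    seed = seed,
    design = list(n_per_cell = 4, suctions_kPa = c(1.5, 15, 50)),
    peaks = list(n_peaks = 300, noise_frac = 0.1, mass_error_ppm = 0.2,
                 drift_ppm = c(0, 0), library_per_class = 300),
    chamber = list(V = 2e4, M = 100, Pa = 101.325, T = 295.15,
                   R = GAS_CONSTANT_CM3),
    gas = list(dt_s = 60, duration_min = 1400, tau_s = 14400,
               flux_cv = 0.2),
    tolerances = list(snr = 7, ppm = 1),
    scheme_precedence = schemePrecedence(vanKrevelenScheme()),
    flux_windows = list(rewet_s = 300, post_s = 1800),
    stats = list(ddf = "Satterthwaite",
                 transforms = list(proteins = "log",
                                   carbohydrates = "log",
                                   tannins = "log",
                                   ch4_ugC = "log"))
  )
}

#' Read and validate a run configuration file
#'
#' YAML config; keys are checked recursively against
#' [defaultRunConfig()] and unknown keys are rejected. Missing keys
#' fall back to the defaults.
#'
#' @param path YAML file.
#' @return Config list.
#' @export
readRunConfig <- function(path) {
  user <- yaml::read_yaml(path)
  def <- defaultRunConfig()
  merge <- function(d, u, prefix = "") {
    unknown <- setdiff(names(u), names(d))
    if (length(unknown))
      stop("unknown config key(s): ",
           paste0(prefix, unknown, collapse = ", "))
    for (k in names(u)) {
      d[[k]] <- if (is.list(d[[k]]) && is.list(u[[k]]))
        merge(d[[k]], u[[k]], paste0(prefix, k, ".")) else u[[k]]
    }
    d
  }
  cfg <- merge(def, user)
  tol <- unlist(cfg$tolerances)
  if (any(tol <= 0)) stop("every tolerance must be positive")
  cfg
}

#' Generate a synthetic dataset directory
#'
#' Runs [genExperiment()] under the config and writes the dataset as
#' plain text: `design.csv`, one peak-list CSV per sample under
#' `peaks/`, one gas-series CSV per core x structure under `gas/`,
#' truth tables under `truth/`, and `manifest.yaml` recording the seed
#' and every effect size. Idempotent under the same seed.
#'
#' @param config list from [defaultRunConfig()] or [readRunConfig()].
#' @param dir output directory (created).
#' @return `dir`, invisibly.
#' @export
runSynthetic <- function(config = defaultRunConfig(), dir) {
  for (sub in c("", "peaks", "gas", "truth"))
    dir.create(file.path(dir, sub), recursive = TRUE,
               showWarnings = FALSE)
  ch <- do.call(chamberSpec, config$chamber)
  design <- treatmentDesign(config$design$n_per_cell,
                            config$design$suctions_kPa)
  lib <- genFormulaLibrary(config$peaks$library_per_class,
                           seed = config$seed)
  ex <- genExperiment(design, n_peaks = config$peaks$n_peaks,
                      noise_frac = config$peaks$noise_frac,
                      mass_error_ppm = config$peaks$mass_error_ppm,
                      drift_ppm = config$peaks$drift_ppm,
                      fluxCV = config$gas$flux_cv, chamber = ch,
                      dt_s = config$gas$dt_s,
                      duration_min = config$gas$duration_min,
                      tau_s = config$gas$tau_s, library = lib,
                      seed = config$seed)
  write.csv(ex$design, file.path(dir, "design.csv"), row.names = FALSE)
  for (sid in names(ex$peakLists))
    writePeakList(ex$peakLists[[sid]],
                  file.path(dir, "peaks", paste0(sid, ".csv")))
  for (gid in names(ex$gasSeries)) {
    d <- seriesData(ex$gasSeries[[gid]])
    out <- data.frame(time_s = d$time_s, co2_ppm = d$co2 * 1e6,
                      ch4_ppm = d$ch4 * 1e6)
    write.csv(out, file.path(dir, "gas", paste0(gid, ".csv")),
              row.names = FALSE)
  }
  truthF <- do.call(rbind, lapply(names(ex$truth$formulas), function(s)
    cbind(sample_id = s, ex$truth$formulas[[s]])))
  write.csv(truthF, file.path(dir, "truth", "formulas.csv"),
            row.names = FALSE)
  write.csv(ex$truth$flux, file.path(dir, "truth", "flux.csv"),
            row.names = FALSE)
  yaml::write_yaml(config, file.path(dir, "manifest.yaml"))
  invisible(dir)
}

.logLine <- function(log, ...) {
  msg <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ...)
  cat(msg, "\n", file = log, append = TRUE)
}

#' Analyze a dataset directory
#'
#' Runs the full processing chain on a directory produced by
#' [runSynthetic()] (or laid out the same way): FT-ICR stages (read,
#' S/N filter, internal calibration, formula assignment,
#' classification, profiles), gas stages (windowed slopes, fluxes,
#' cumulative emissions, a treatment-mean summary), and the inference
#' layer (PCA, per-fraction REML models, gas REML models, LSD letters,
#' ratio contrasts). Stages whose inputs are absent are skipped with a
#' notice in the log. Results are CSV files plus `log.txt` in `outDir`.
#'
#' @param dir dataset directory (must contain `manifest.yaml`).
#' @param outDir results directory (created).
#' @return `outDir`, invisibly.
#' @export
runAnalysis <- function(dir, outDir = file.path(dir, "results")) {
  manifestPath <- file.path(dir, "manifest.yaml")
  if (!file.exists(manifestPath))
    stop("no manifest.yaml in ", dir)
  cfg <- readRunConfig(manifestPath)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  log <- file.path(outDir, "log.txt")
  cat("", file = log)
  .logLine(log, "run start; seed ", cfg$seed, "; ddf ", cfg$stats$ddf,
           "; snr>", cfg$tolerances$snr, "; ppm<", cfg$tolerances$ppm,
           "; precedence ",
           paste(cfg$scheme_precedence, collapse = ">"))
  scheme <- vanKrevelenScheme(cfg$scheme_precedence)
  design <- if (file.exists(file.path(dir, "design.csv")))
    read.csv(file.path(dir, "design.csv")) else NULL
  ch <- do.call(chamberSpec, cfg$chamber)

  # ---- FT-ICR stage ----
  peakFiles <- list.files(file.path(dir, "peaks"), full.names = TRUE,
                          pattern = "\\.csv$")
  profiles <- NULL
  if (length(peakFiles)) {
    assignList <- list(); profList <- list()
    for (f in peakFiles) {
      pl <- tryCatch(readPeakList(f), error = function(e)
        stop("FT-ICR stage failed on ", f, ": ", conditionMessage(e)))
      pl <- filterSNR(pl, cfg$tolerances$snr)
      cal <- suppressWarnings(calibrateInternal(pl))
      asg <- assignFormulas(cal$peakList,
                            tolerancePpm = cfg$tolerances$ppm,
                            scheme = scheme)
      if (nrow(asg) == 0) {
        .logLine(log, "no assignments for ", sampleId(pl))
        next
      }
      assignList[[sampleId(pl)]] <- cbind(sample_id = sampleId(pl), asg)
      profList[[sampleId(pl)]] <-
        abundanceProfile(asg, scheme, sampleId(pl))
    }
    assignments <- do.call(rbind, assignList)
    profiles <- do.call(rbind, profList)
    rownames(profiles) <- NULL
    write.csv(assignments, file.path(outDir, "assignments.csv"),
              row.names = FALSE)
    write.csv(profiles, file.path(outDir, "profiles.csv"),
              row.names = FALSE)
    .logLine(log, "fticr: ", length(peakFiles), " samples, ",
             nrow(assignments), " assignments")
  } else .logLine(log, "fticr: no peak lists found, stage skipped")

  # ---- gas stage ----
  gasFiles <- list.files(file.path(dir, "gas"), full.names = TRUE,
                         pattern = "\\.csv$")
  cumul <- NULL
  if (length(gasFiles)) {
    rows <- list()
    for (f in gasFiles) {
      gid <- sub("\\.csv$", "", basename(f))
      d <- read.csv(f)
      ser <- headspaceSeries(d$time_s, d$co2_ppm * 1e-6,
                             d$ch4_ppm * 1e-6, coreId = gid)
      ce <- cumulativeEmission(ser, ch,
                               rewetWindow_s = cfg$flux_windows$rewet_s,
                               postWindow_s = cfg$flux_windows$post_s)
      fs <- fluxSeries(ser, ch,
                       rewetWindow_s = cfg$flux_windows$rewet_s,
                       postWindow_s = cfg$flux_windows$post_s)
      write.csv(cbind(series_id = gid, fs),
                file.path(outDir, paste0("flux_", gid, ".csv")),
                row.names = FALSE)
      rows[[gid]] <- data.frame(series_id = gid,
                                co2_mgC = ce$co2_mgC,
                                ch4_ugC = ce$ch4_ugC)
    }
    cumul <- do.call(rbind, rows)
    rownames(cumul) <- NULL
    if (!is.null(design)) {
      meta <- unique(design[, c("core_id", "moisture", "wetting",
                                "structure")])
      meta$series_id <- paste(meta$core_id, meta$structure, sep = "_")
      cumul <- merge(cumul, meta, by = "series_id", sort = TRUE)
    }
    write.csv(cumul, file.path(outDir, "cumulative.csv"),
              row.names = FALSE)
    .logLine(log, "gasflux: ", length(gasFiles), " series")
    if (!is.null(design)) {
      agg <- aggregate(cbind(co2_mgC, ch4_ugC) ~
                         moisture + wetting + structure, cumul, mean)
      se <- aggregate(cbind(co2_mgC, ch4_ugC) ~
                        moisture + wetting + structure, cumul,
                      function(v) sd(v) / sqrt(length(v)))
      names(se)[4:5] <- c("co2_mgC_se", "ch4_ugC_se")
      summaryTab <- merge(agg, se)
      write.csv(summaryTab, file.path(outDir, "emission_summary.csv"),
                row.names = FALSE)
    }
  } else .logLine(log, "gasflux: no gas series found, stage skipped")

  # ---- inference stage ----
  if (!is.null(profiles) && !is.null(design) && nrow(profiles) >= 3) {
    se <- profilesToSE(profiles, design, scheme)
    pca <- pcaProfiles(se)
    write.csv(data.frame(sample_id = rownames(pca$scores), pca$scores),
              file.path(outDir, "pca_scores.csv"), row.names = FALSE)
    write.csv(data.frame(variable = rownames(pca$loadingCor),
                         pca$loadingCor),
              file.path(outDir, "pca_loading_correlations.csv"),
              row.names = FALSE)
    tab <- merge(profiles, design, by = "sample_id")
    fracRows <- list()
    responses <- c(classLabels(scheme), "richness")
    for (su in unique(tab$suction_kPa)) {
      sub <- tab[tab$suction_kPa == su, , drop = FALSE]
      for (resp in responses) {
        if (length(unique(sub[[resp]])) < 3) next
        trans <- cfg$stats$transforms[[resp]]
        if (is.null(trans)) trans <- "identity"
        fit <- tryCatch(
          fitLMM(sub, resp,
                 c("moisture", "wetting", "structure",
                   "moisture:wetting"),
                 transform = trans, offset = "auto",
                 ddf = cfg$stats$ddf),
          error = function(e) NULL)
        if (is.null(fit)) next
        a <- fit$anova
        a$suction_kPa <- su; a$response <- resp
        a$transform <- fit$transform
        fracRows[[paste(su, resp)]] <- a
      }
    }
    if (length(fracRows))
      write.csv(do.call(rbind, c(fracRows, make.row.names = FALSE)),
                file.path(outDir, "lmm_fractions.csv"),
                row.names = FALSE)
    .logLine(log, "stats: PCA + ", length(fracRows),
             " per-fraction models")
  } else .logLine(log, "stats: FT-ICR inference skipped (no profiles)")

  if (!is.null(cumul) && "moisture" %in% names(cumul)) {
    gasRows <- list(); lsdRows <- list()
    for (st in unique(cumul$structure)) {
      sub <- cumul[cumul$structure == st, , drop = FALSE]
      for (resp in c("co2_mgC", "ch4_ugC")) {
        trans <- cfg$stats$transforms[[resp]]
        if (is.null(trans)) trans <- "identity"
        fit <- tryCatch(
          fitLMM(sub, resp, c("moisture", "wetting",
                              "moisture:wetting"),
                 transform = trans, offset = "auto",
                 ddf = cfg$stats$ddf),
          error = function(e) NULL)
        if (is.null(fit)) next
        a <- fit$anova; a$structure <- st; a$response <- resp
        gasRows[[paste(st, resp)]] <- a
        grp <- tryCatch(lsdGroups(fit, c("moisture", "wetting")),
                        error = function(e) NULL)
        if (!is.null(grp)) {
          grp$structure <- st; grp$response <- resp
          lsdRows[[paste(st, resp)]] <- grp
        }
      }
    }
    if (length(gasRows))
      write.csv(do.call(rbind, c(gasRows, make.row.names = FALSE)),
                file.path(outDir, "lmm_gas.csv"), row.names = FALSE)
    if (length(lsdRows))
      write.csv(do.call(rbind, c(lsdRows, make.row.names = FALSE)),
                file.path(outDir, "lsd_gas.csv"), row.names = FALSE)
    agg <- aggregate(cbind(co2_mgC, ch4_ugC) ~ moisture + wetting,
                     cumul[cumul$structure == "intact", ], mean)
    ratios <- tryCatch(ratioTable(agg), error = function(e) NULL)
    if (!is.null(ratios))
      write.csv(ratios, file.path(outDir, "ratios.csv"),
                row.names = FALSE)
    .logLine(log, "stats: gas models + ratio contrasts done")
  }
  .logLine(log, "run complete")
  invisible(outDir)
}

#' Human-readable markdown report of a results directory
#'
#' Collates the analysis outputs into a markdown summary: emission
#' means with LSD letters, ratio contrasts, PCA loading correlations
#' and per-fraction model P-values. Missing pieces produce warnings and
#' a partial report rather than an error.
#'
#' @param resultsDir directory written by [runAnalysis()].
#' @param file optional output path; default `report.md` inside
#'   `resultsDir`.
#' @return The report text, invisibly.
#' @export
reportRun <- function(resultsDir, file = file.path(resultsDir,
                                                   "report.md")) {
  rd <- function(name) {
    p <- file.path(resultsDir, name)
    if (file.exists(p)) read.csv(p) else {
      warning("missing results file: ", name)
      NULL
    }
  }
  fmt <- function(df) {
    if (is.null(df)) return("_not available_\n")
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], signif, 4)
    paste(c(paste("|", paste(names(df), collapse = " | "), "|"),
            paste("|", paste(rep("---", ncol(df)), collapse = " | "),
                  "|"),
            apply(df, 1, function(r)
              paste("|", paste(r, collapse = " | "), "|"))),
          collapse = "\n")
  }
  parts <- c(
    "# Rewetting experiment analysis report", "",
    "## Cumulative emissions (treatment means)", "",
    fmt(rd("emission_summary.csv")), "",
    "## LSD letter displays", "", fmt(rd("lsd_gas.csv")), "",
    "## Treatment ratio contrasts", "", fmt(rd("ratios.csv")), "",
    "## PCA loading correlations (%)", "",
    fmt(rd("pca_loading_correlations.csv")), "",
    "## Per-fraction mixed models", "", fmt(rd("lmm_fractions.csv")),
    "")
  txt <- paste(parts, collapse = "\n")
  writeLines(txt, file)
  invisible(txt)
}
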