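#' Generate a library of CHONSP formulas grouped by compound class
#'
#' Builds, by rejection sampling, `n_per_class` distinct neutral formulas
#' for each of the eight Van Krevelen classes plus the unnamed region.
#' Every formula satisfies: (O/C, H/C) strictly inside the sampling
#' region of its class (so re-classification under the scheme precedence
#' recovers the label exactly), neutral monoisotopic mass in
#' (201, 1199) Da, integer DBE >= 0, and the element bounds C 4-70,
#' H 4-140, O 0-40, N 0-4, S 0-2, P 0-2.
#'
#' The lipid region starts above O/C = 0.125 because the
#' unsaturated-hydrocarbon box takes precedence below it; the unnamed
#' region sits at O/C 1.15-1.45, H/C 0.85-1.45, outside all eight boxes.
#'
#' @param n_per_class number of formulas per class (>= 1).
#' @param seed integer RNG seed.
#' @param scheme [ClassScheme-class] used to verify labels.
#' @param maxAttempts rejection-sampling budget per class.
#' @return data.frame with columns `class`, `C`, `H`, `O`, `N`, `S`,
#'   `P`, `formula`, `neutral_mass`, `oc`, `hc`, `dbe`.
#' @examples
#' lib <- genFormulaLibrary(1, seed = 7)
#' table(lib$class)  # one formula in each of the 9 regions
#' @export
genFormulaLibrary <- function(n_per_class, seed = 1,
                              scheme = vanKrevelenScheme(),
                              maxAttempts = 20000) {
  stopifnot(n_per_class >= 1)
  set.seed(seed)
  regions <- list(
    lipids                   = list(oc = c(0.13, 0.29), hc = c(1.55, 2.45)),
    unsaturated_hydrocarbons = list(oc = c(0.00, 0.12), hc = c(0.85, 2.40)),
    proteins                 = list(oc = c(0.31, 0.54), hc = c(1.55, 2.25)),
    amino_sugars             = list(oc = c(0.56, 0.69), hc = c(1.55, 2.15)),
    carbohydrates            = list(oc = c(0.71, 1.05), hc = c(1.55, 2.45)),
    lignin                   = list(oc = c(0.15, 0.64), hc = c(0.85, 1.45)),
    tannins                  = list(oc = c(0.66, 1.09), hc = c(0.85, 1.45)),
    condensed_hydrocarbons   = list(oc = c(0.00, 0.90), hc = c(0.25, 0.75)),
    unnamed                  = list(oc = c(1.15, 1.45), hc = c(0.85, 1.45))
  )
  out <- vector("list", length(regions))
  names(out) <- names(regions)
  for (cl in names(regions)) {
    reg <- regions[[cl]]
    got <- character(0)
    rows <- vector("list", n_per_class)
    attempts <- 0
    while (length(got) < n_per_class) {
      attempts <- attempts + 1
      if (attempts > maxAttempts)
        stop("class region '", cl, "' admits no further valid formulas ",
             "under the element bounds (", length(got), "/", n_per_class,
             " found)")
      C <- sample(10:45, 1)
      O <- round(C * runif(1, reg$oc[1], reg$oc[2]))
      N <- sample(0:2, 1, prob = c(0.6, 0.3, 0.1))
      S <- sample(0:1, 1, prob = c(0.92, 0.08))
      H <- round(C * runif(1, reg$hc[1], reg$hc[2]))
      if ((H + N) %% 2 != 0) H <- H + sample(c(-1L, 1L), 1)
      if (H < 4 || H > 140 || O < 0 || O > 40) next
      oc <- O / C; hc <- H / C
      # strict interior of the sampling region (O/C = 0 allowed for
      # hydrocarbons, whose boxes close at zero)
      ocOk <- (oc > reg$oc[1] || (reg$oc[1] == 0 && oc >= 0)) &&
        oc < reg$oc[2]
      if (!ocOk || hc <= reg$hc[1] || hc >= reg$hc[2]) next
      dbe <- formulaDBE(C, H, N, 0)
      if (dbe < 0 || dbe != round(dbe)) next
      mass <- formulaMass(C, H, O, N, S, 0)
      if (mass <= 201 || mass >= 1199) next
      if (classifyFormulas(oc, hc, scheme) != cl) next
      f <- formulaString(C, H, O, N, S, 0)
      if (f %in% got) next
      # accept, then extend into a CH2 homologous series while it stays
      # valid: natural OM spectra are dominated by such series, and the
      # internal-calibration stage depends on finding them
      chain <- 0
      while (length(got) < n_per_class && chain < 8) {
        got <- c(got, f)
        rows[[length(got)]] <- data.frame(
          class = cl, C = C, H = H, O = O, N = N, S = S, P = 0L,
          formula = f, neutral_mass = mass, oc = oc, hc = hc, dbe = dbe)
        chain <- chain + 1
        C <- C + 1L; H <- H + 2L
        oc <- O / C; hc <- H / C
        mass <- formulaMass(C, H, O, N, S, 0)
        ocOk <- (oc > reg$oc[1] || (reg$oc[1] == 0 && oc >= 0)) &&
          oc < reg$oc[2]
        if (!ocOk || hc <= reg$hc[1] || hc >= reg$hc[2] ||
            H > 140 || mass >= 1199 ||
            classifyFormulas(oc, hc, scheme) != cl) break
        f <- formulaString(C, H, O, N, S, 0)
        if (f %in% got) break
      }
    }
    out[[cl]] <- do.call(rbind, rows)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
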