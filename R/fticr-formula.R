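#' Element count bounds for the CHONSP formula search
#'
#' Defaults span natural organic matter within the 200-1200 Da window:
#' C 1-70, H 1-140, O 0-40, N 0-4, S 0-2, P 0-2. Elemental-ratio sanity
#' limits in the tradition of the "golden rules" for formula filtering
#' (0.2 <= H/C <= 3.1, O/C <= 2.5, N/C <= 1.3, S/C <= 0.8, P/C <= 0.3)
#' a combined heteroatom cap (N+S+P <= 5), and a phosphate constraint
#' (P only with O >= 4 per P, since organic P in natural organic matter
#' is phosphate-like) prune chemically absurd candidates; without them,
#' sub-mDa heteroatom-stuffed isobars (e.g. swapping C5O6 for H5N4S2P)
#' dominate the sub-ppm search space.
#'
#' @param maxC,maxH,maxO,maxN,maxS,maxP upper element counts.
#' @param minHC,maxHC,maxOC,maxNC,maxSC,maxPC ratio sanity limits.
#' @param maxHet combined N+S+P cap.
#' @param minOperP minimum O per P atom.
#' @return Named list of bounds.
#' @export
elementBounds <- function(maxC = 70, maxH = 140, maxO = 40, maxN = 4,
                          maxS = 2, maxP = 2, minHC = 0.2, maxHC = 3.1,
                          maxOC = 2.5, maxNC = 1.3, maxSC = 0.8,
                          maxPC = 0.3, maxHet = 5, minOperP = 4) {
  list(maxC = maxC, maxH = maxH, maxO = maxO, maxN = maxN, maxS = maxS,
       maxP = maxP, minHC = minHC, maxHC = maxHC, maxOC = maxOC,
       maxNC = maxNC, maxSC = maxSC, maxPC = maxPC, maxHet = maxHet,
       minOperP = minOperP)
}

#' Exact monoisotopic mass of a neutral CHONSP formula
#'
#' @param C,H,O,N,S,P element counts (vectors, recycled).
#' @return Neutral monoisotopic mass in Da.
#' @examples
#' formulaMass(C = 16, H = 32, O = 2)  # palmitic acid, 256.24023
#' @export
formulaMass <- function(C, H, O = 0, N = 0, S = 0, P = 0) {
  C * ELEMENT_MASSES[["C"]] + H * ELEMENT_MASSES[["H"]] +
    O * ELEMENT_MASSES[["O"]] + N * ELEMENT_MASSES[["N"]] +
    S * ELEMENT_MASSES[["S"]] + P * ELEMENT_MASSES[["P"]]
}

#' Double-bond equivalents of a CHONSP neutral
#'
#' DBE = C - H/2 + N/2 + P/2 + 1. Even-electron neutral formulas have an
#' integer DBE; the assignment search only accepts those.
#'
#' @param C,H,N,P element counts.
#' @return Numeric DBE (may be half-integer for invalid formulas).
#' @export
formulaDBE <- function(C, H, N = 0, P = 0) {
  C - H / 2 + N / 2 + P / 2 + 1
}

#' Molecular formula string in Hill-like CHONSP order
#'
#' @param C,H,O,N,S,P element counts (vectors).
#' @return Character vector, e.g. `"C16H32O2"`.
#' @export
formulaString <- function(C, H, O = 0, N = 0, S = 0, P = 0) {
  part <- function(sym, n) ifelse(n > 0, paste0(sym, n), "")
  paste0(part("C", C), part("H", H), part("O", O), part("N", N),
         part("S", S), part("P", P))
}

# Candidate grid over (C, O, N, S, P) with H left free; cached per bounds.
# basemass is the mass of the H-free skeleton, sorted ascending.
.gridCache <- new.env(parent = emptyenv())

.candidateGrid <- function(bounds, maxMass = 1200) {
  key <- paste(unlist(bounds), maxMass, collapse = "_")
  if (!is.null(.gridCache[[key]])) return(.gridCache[[key]])
  g <- expand.grid(C = seq_len(bounds$maxC), O = 0:bounds$maxO,
                   N = 0:bounds$maxN, S = 0:bounds$maxS, P = 0:bounds$maxP,
                   KEEP.OUT.ATTRS = FALSE)
  g <- g[g$O <= bounds$maxOC * g$C &
           g$N <= bounds$maxNC * g$C &
           g$S <= bounds$maxSC * g$C &
           g$P <= bounds$maxPC * g$C &
           g$N + g$S + g$P <= bounds$maxHet &
           g$O >= bounds$minOperP * g$P, , drop = FALSE]
  g$basemass <- formulaMass(g$C, 0, g$O, g$N, g$S, g$P)
  g <- g[g$basemass + ELEMENT_MASSES[["H"]] <= maxMass, , drop = FALSE]
  g <- g[order(g$basemass), , drop = FALSE]
  rownames(g) <- NULL
  if (nrow(g) == 0)
    stop("element bounds admit no candidate composition")
  .gridCache[[key]] <- g
  g
}

#' Assign molecular formulas to negative-mode peaks
#'
#' For every peak inside the m/z window the neutral mass is computed by
#' adding one proton mass ([M-H]- deprotonation) and an exhaustive search
#' over CHONSP compositions within the element bounds is performed.
#' Candidates must lie within the ppm tolerance, have C >= 1, H >= 1,
#' an integer DBE >= 0 (even-electron neutrals only) and pass the
#' elemental-ratio sanity limits. Among surviving candidates the winner
#' is chosen by smallest absolute mass error, then fewest heteroatoms
#' (N+S+P), then lowest DBE. Peaks with no candidate are dropped.
#'
#' @param x a [PeakList-class] (apply [filterSNR()] and
#'   [calibrateInternal()] first) or a data.frame with an `mz` column.
#' @param tolerancePpm assignment tolerance; candidates must satisfy
#'   |error| < `tolerancePpm` (strict), default 1 ppm.
#' @param bounds element bounds from [elementBounds()].
#' @param mzWindow open interval of m/z values considered, default
#'   (200, 1200).
#' @param scheme [ClassScheme-class] used to attach compound classes.
#' @return data.frame with one row per assigned peak: `mz`, `intensity`,
#'   `snr` (when available), element counts `C`,`H`,`O`,`N`,`S`,`P`,
#'   `formula`, `neutral_mass` (theoretical), `error_ppm` (observed vs
#'   theoretical m/z), `oc`, `hc`, `dbe`, `class`, and `n_candidates`
#'   (number of in-tolerance candidates the tie-break saw).
#' @examples
#' pl <- PeakList(mz = 255.23295, intensity = 1, snr = 100)
#' assignFormulas(pl)[, c("formula", "error_ppm", "class")]
#' @export
assignFormulas <- function(x, tolerancePpm = 1,
                           bounds = elementBounds(),
                           mzWindow = c(200, 1200),
                           scheme = vanKrevelenScheme()) {
  if (is(x, "PeakList")) {
    if (polarity(x) != "negative")
      stop("only negative-mode peak lists are supported")
    p <- peaks(x)
  } else {
    p <- as.data.frame(x)
    if (!"mz" %in% names(p)) stop("x must have an 'mz' column")
    if (is.null(p$intensity)) p$intensity <- NA_real_
    if (is.null(p$snr)) p$snr <- NA_real_
  }
  stopifnot(tolerancePpm > 0)
  p <- p[p$mz > mzWindow[1] & p$mz < mzWindow[2], , drop = FALSE]
  if (nrow(p) == 0)
    return(.emptyAssignment())
  grid <- .candidateGrid(bounds, maxMass = mzWindow[2] + PROTON_MASS + 1)
  mH <- ELEMENT_MASSES[["H"]]
  rows <- vector("list", nrow(p))
  for (i in seq_len(nrow(p))) {
    m <- p$mz[i] + PROTON_MASS            # neutral target mass
    tolDa <- tolerancePpm * 1e-6 * p$mz[i]
    lo <- findInterval(m - bounds$maxH * mH - tolDa, grid$basemass) + 1L
    hi <- findInterval(m - mH + tolDa, grid$basemass)
    if (hi < lo) next
    idx <- lo:hi
    H <- round((m - grid$basemass[idx]) / mH)
    ok <- H >= 1 & H <= bounds$maxH &
      H <= bounds$maxHC * grid$C[idx] &
      H >= bounds$minHC * grid$C[idx] &
      (H + grid$N[idx] + grid$P[idx]) %% 2 == 0
    idx <- idx[ok]; H <- H[ok]
    if (!length(idx)) next
    dbe <- formulaDBE(grid$C[idx], H, grid$N[idx], grid$P[idx])
    ok <- dbe >= 0
    idx <- idx[ok]; H <- H[ok]; dbe <- dbe[ok]
    if (!length(idx)) next
    neutral <- grid$basemass[idx] + H * mH
    thMz <- neutral - PROTON_MASS
    errPpm <- (p$mz[i] - thMz) / thMz * 1e6
    ok <- abs(errPpm) < tolerancePpm
    idx <- idx[ok]; H <- H[ok]; dbe <- dbe[ok]
    neutral <- neutral[ok]; errPpm <- errPpm[ok]
    if (!length(idx)) next
    het <- grid$N[idx] + grid$S[idx] + grid$P[idx]
    best <- order(abs(errPpm), het, dbe)[1]
    rows[[i]] <- data.frame(
      mz = p$mz[i], intensity = p$intensity[i], snr = p$snr[i],
      C = grid$C[idx[best]], H = H[best], O = grid$O[idx[best]],
      N = grid$N[idx[best]], S = grid$S[idx[best]], P = grid$P[idx[best]],
      neutral_mass = neutral[best], error_ppm = errPpm[best],
      dbe = dbe[best], n_candidates = length(idx))
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) return(.emptyAssignment())
  out$formula <- formulaString(out$C, out$H, out$O, out$N, out$S, out$P)
  out$oc <- out$O / out$C
  out$hc <- out$H / out$C
  out$class <- classifyFormulas(out$oc, out$hc, scheme)
  rownames(out) <- NULL
  out
}

.emptyAssignment <- function() {
  data.frame(mz = numeric(), intensity = numeric(), snr = numeric(),
             C = integer(), H = integer(), O = integer(), N = integer(),
             S = integer(), P = integer(), neutral_mass = numeric(),
             error_ppm = numeric(), dbe = numeric(),
             n_candidates = integer(), formula = character(),
             oc = numeric(), hc = numeric(), class = character())
}
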