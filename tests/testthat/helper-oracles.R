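# Independent brute-force formula enumerator used as the oracle for
# assignFormulas. Deliberately organized differently from the package
# implementation: it loops over (C, N, S, P), vectorizes over H, and
# solves for the oxygen count from the residual mass, instead of
# gridding (C, O, N, S, P) and solving for H.
oracleCandidates <- function(mz, tolPpm = 1, bounds = elementBounds()) {
  mH <- 1.00782503207; mO <- 15.9949146196
  mC <- 12; mN <- 14.0030740048; mS <- 31.97207100; mP <- 30.97376163
  proton <- 1.00727646677
  m <- mz + proton
  out <- list()
  for (C in seq_len(bounds$maxC)) {
    Hmax <- min(bounds$maxH, floor(bounds$maxHC * C))
    Hmin <- max(1, ceiling(bounds$minHC * C))
    if (Hmax < Hmin) next
    H <- Hmin:Hmax
    for (N in 0:bounds$maxN) for (S in 0:bounds$maxS)
      for (P in 0:bounds$maxP) {
        if (N > bounds$maxNC * C || S > bounds$maxSC * C ||
            P > bounds$maxPC * C || N + S + P > bounds$maxHet) next
        rem <- m - (C * mC + H * mH + N * mN + S * mS + P * mP)
        O <- round(rem / mO)
        ok <- O >= 0 & O <= bounds$maxO & O <= bounds$maxOC * C &
          O >= bounds$minOperP * P & (H + N + P) %% 2 == 0
        if (!any(ok)) next
        th <- C * mC + H[ok] * mH + O[ok] * mO + N * mN + S * mS + P * mP
        err <- (m - th) / (th - proton) * 1e6
        dbe <- C - H[ok] / 2 + N / 2 + P / 2 + 1
        keep <- abs(err) < tolPpm & dbe >= 0
        if (!any(keep)) next
        out[[length(out) + 1]] <- data.frame(
          C = C, H = H[ok][keep], O = O[ok][keep], N = N, S = S, P = P,
          error_ppm = err[keep], dbe = dbe[keep])
      }
  }
  if (!length(out)) return(NULL)
  do.call(rbind, out)
}

# oracle's winner under the documented tie-break: smallest |error|,
# then fewest heteroatoms, then lowest DBE
oracleBest <- function(mz, tolPpm = 1, bounds = elementBounds()) {
  cand <- oracleCandidates(mz, tolPpm, bounds)
  if (is.null(cand)) return(NULL)
  het <- cand$N + cand$S + cand$P
  cand[order(abs(cand$error_ppm), het, cand$dbe)[1], , drop = FALSE]
}

# shared formula library, built once per test run
sharedLibrary <- local({
  lib <- NULL
  function() {
    if (is.null(lib)) lib <<- genFormulaLibrary(220, seed = 101)
    lib
  }
})

# small balanced 16-core table with a planted interaction of size
# `gamma` (sum-to-zero coding) on top of unit-SD residual noise
simulateCores <- function(gamma = 0, sigma = 1, nPerCell = 4) {
  d <- expand.grid(rep = seq_len(nPerCell),
                   moisture = c("field", "drought"),
                   wetting = c("top_precipitation", "bottom_groundwater"),
                   stringsAsFactors = FALSE)
  d$core_id <- sprintf("C%02d", seq_len(nrow(d)))
  sgn <- ifelse(d$moisture == "drought", 1, -1) *
    ifelse(d$wetting == "top_precipitation", 1, -1)
  d$y <- 100 + gamma * sgn + rnorm(nrow(d), 0, sigma)
  d
}
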