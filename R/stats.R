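#' Principal components of compound-class profiles
#'
#' PCA on centered, unit-variance class relative abundances. For each
#' axis the per-variable "loading correlation" is reported: the Pearson
#' correlation (as a percentage) between the variable and the axis
#' scores. The sign convention fixes each axis so its
#' largest-|correlation| variable correlates positively.
#'
#' @param x a `SummarizedExperiment` from [profilesToSE()] (assay
#'   `"relabund"`, variables in rows) or a data.frame/matrix with
#'   samples in rows and class variables in columns.
#' @param nComponents number of components to report.
#' @return Object of class `"PCAResult"`: list with `scores` (samples x
#'   components), `loadingCor` (variables x components, percent),
#'   `varianceExplained` (fraction per component) and `variables`.
#' @examples
#' m <- rbind(a = c(1, 0, .2), b = c(.9, .1, .25),
#'            c = c(.1, .9, .8), d = c(0, 1, .9))
#' colnames(m) <- c("lignin", "unnamed", "lipids")
#' pcaProfiles(m)$loadingCor
#' @export
pcaProfiles <- function(x, nComponents = 2) {
  if (is(x, "SummarizedExperiment"))
    m <- t(SummarizedExperiment::assay(x, "relabund"))
  else
    m <- as.matrix(x)
  if (nrow(m) < 3) stop("need at least 3 samples")
  v <- apply(m, 2, stats::var)
  m <- m[, v > 0, drop = FALSE]
  if (ncol(m) < 2)
    stop("need at least 2 class variables with nonzero variance")
  nComponents <- min(nComponents, ncol(m), nrow(m) - 1)
  pc <- prcomp(m, center = TRUE, scale. = TRUE)
  scores <- pc$x[, seq_len(nComponents), drop = FALSE]
  lc <- cor(m, scores) * 100
  for (j in seq_len(ncol(scores))) {
    top <- which.max(abs(lc[, j]))
    if (lc[top, j] < 0) {
      scores[, j] <- -scores[, j]
      lc[, j] <- -lc[, j]
    }
  }
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(scores = scores, loadingCor = lc,
                 varianceExplained = ve[seq_len(nComponents)],
                 variables = colnames(m)),
            class = "PCAResult")
}

#' @export
print.PCAResult <- function(x, ...) {
  cat(sprintf("PCA of %d variables: %s variance explained\n",
              length(x$variables),
              paste(sprintf("%.1f%%", 100 * x$varianceExplained),
                    collapse = " + ")))
  print(round(x$loadingCor, 1))
  invisible(x)
}

# ---- transformations ---------------------------------------------------

#' Response transformations for mixed models
#'
#' `identity`; `log` (natural log; zero or negative values are an error
#' unless an offset is supplied or `offset = "auto"`, which adds half
#' the smallest positive value); `reciprocal_log`, implemented as
#' 1/log(y + c) with c chosen so every argument of the log exceeds 1
#' (recorded in the result).
#'
#' @param y numeric response.
#' @param transform one of `"identity"`, `"log"`, `"reciprocal_log"`.
#' @param offset numeric offset, `"auto"`, or `NULL` (the default:
#'   error if `log` needs one).
#' @return List with `y` (transformed), `transform`, `offset` (the
#'   constant actually added) and `inverse` (a function mapping the
#'   model scale back to the response scale).
#' @export
applyTransform <- function(y, transform = c("identity", "log",
                                            "reciprocal_log"),
                           offset = NULL) {
  transform <- match.arg(transform)
  if (transform == "identity")
    return(list(y = y, transform = transform, offset = 0,
                inverse = identity))
  if (transform == "log") {
    c0 <- 0
    if (any(y <= 0)) {
      if (is.null(offset))
        stop("log transform with nonpositive values: supply offset = ",
             "\"auto\" (half the smallest positive value) or a number")
      c0 <- if (identical(offset, "auto"))
        min(y[y > 0]) / 2 else as.numeric(offset)
    } else if (is.numeric(offset)) c0 <- offset
    return(list(y = log(y + c0), transform = transform, offset = c0,
                inverse = function(z) exp(z) - c0))
  }
  # reciprocal_log: 1/log(y + c), c such that min(y + c) > 1
  c0 <- if (is.numeric(offset)) as.numeric(offset)
        else max(0, 1.01 - min(y))
  if (min(y + c0) <= 1)
    stop("reciprocal_log offset leaves arguments <= 1")
  list(y = 1 / log(y + c0), transform = transform, offset = c0,
       inverse = function(z) exp(1 / z) - c0)
}

# ---- REML mixed models -------------------------------------------------

#' REML linear mixed model with core as random effect
#'
#' Fits `response ~ fixed terms + (1 | core)` by REML and reports
#' marginal (type III) F tests per fixed term. The default denominator
#' degrees of freedom use the Satterthwaite approximation
#' (Kenward-Roger available via `ddf`); the method used is recorded in
#' the fit. One-observation-per-core designs are allowed: the core
#' variance is then estimated at or near zero and the F tests reduce to
#' the fixed-effects ANOVA.
#'
#' @param table data.frame, one row per observation.
#' @param response response column name.
#' @param fixed character vector of fixed-effect terms, e.g.
#'   `c("moisture", "wetting", "moisture:wetting")` or
#'   `"moisture * wetting"`.
#' @param random grouping column for the random intercept.
#' @param transform,offset passed to [applyTransform()].
#' @param ddf denominator-df method, `"Satterthwaite"` or
#'   `"Kenward-Roger"`.
#' @return Object of class `"MixedModelFit"`: list with `model` (the
#'   `lmerModLmerTest` fit), `anova` (data.frame: term, num_df, den_df,
#'   F, p), `varcomp` (named: core, residual), `transform`, `offset`,
#'   `ddf`, `response`.
#' @examples
#' \donttest{
#' d <- expand.grid(core_id = sprintf("C%02d", 1:16))
#' d$moisture <- rep(c("field", "drought"), each = 8)
#' d$wetting <- rep(rep(c("top", "bottom"), each = 4), 2)
#' set.seed(1); d$y <- rnorm(16)
#' fitLMM(d, "y", "moisture * wetting")$anova
#' }
#' @export
fitLMM <- function(table, response, fixed, random = "core_id",
                   transform = "identity", offset = NULL,
                   ddf = c("Satterthwaite", "Kenward-Roger")) {
  ddf <- match.arg(ddf)
  stopifnot(response %in% names(table), random %in% names(table))
  if (length(unique(table[[random]])) < 2)
    stop("need at least 2 grouping units for the random effect")
  tr <- applyTransform(table[[response]], transform, offset)
  if (any(!is.finite(tr$y)))
    stop("response not finite after transformation")
  dat <- table
  dat$.y <- tr$y
  fixedStr <- paste(fixed, collapse = " + ")
  # fail early on aliased fixed-effect terms
  mm <- stats::model.matrix(as.formula(paste("~", fixedStr)), dat)
  if (qr(mm)$rank < ncol(mm)) {
    ali <- colnames(mm)[-qr(mm)$pivot[seq_len(qr(mm)$rank)]]
    stop("singular fixed-effect design; aliased term(s): ",
         paste(ali, collapse = ", "))
  }
  form <- as.formula(paste(".y ~", fixedStr, "+ (1 |", random, ")"))
  fit <- suppressMessages(suppressWarnings(
    lmerTest::lmer(form, data = dat, REML = TRUE,
                   control = lme4::lmerControl(
                     check.conv.singular = "ignore",
                     check.nobs.vs.nlev = "ignore",
                     check.nobs.vs.nRE = "ignore"))))
  an <- suppressMessages(suppressWarnings(
    stats::anova(fit, type = 3, ddf = ddf)))
  anova_df <- data.frame(term = rownames(an),
                         num_df = an$NumDF, den_df = an$DenDF,
                         F = an$`F value`, p = an$`Pr(>F)`,
                         row.names = NULL)
  vc <- as.data.frame(lme4::VarCorr(fit))
  varcomp <- setNames(vc$vcov, ifelse(vc$grp == "Residual",
                                      "residual", "core"))
  structure(list(model = fit, anova = anova_df, varcomp = varcomp,
                 transform = tr$transform, offset = tr$offset,
                 inverse = tr$inverse, ddf = ddf, response = response,
                 fixed = fixedStr, random = random),
            class = "MixedModelFit")
}

#' @export
print.MixedModelFit <- function(x, ...) {
  cat(sprintf("REML mixed model: %s ~ %s + (1 | %s)  [%s, ddf: %s]\n",
              x$response, x$fixed, x$random, x$transform, x$ddf))
  an <- x$anova
  an$F <- round(an$F, 3); an$p <- signif(an$p, 3)
  print(an)
  cat(sprintf("variance components: core %.4g, residual %.4g\n",
              x$varcomp[["core"]], x$varcomp[["residual"]]))
  invisible(x)
}

# ---- LSD letter displays ----------------------------------------------

# Connected-letter display by insert-and-absorb over the significance
# matrix (sig[i,j] TRUE means cells i and j differ). Each "column" is a
# letter: the set of cells carrying it. Splitting a column on a
# significant pair preserves letter-sharing for all other pairs.
.letterDisplay <- function(labels, sig) {
  n <- length(labels)
  cols <- list(rep(TRUE, n))      # start: everyone shares letter "a"
  for (i in seq_len(max(n - 1, 1))) for (j in seq_len(n)) {
    if (j <= i || !sig[i, j]) next
    for (k in seq_along(cols)) {
      if (cols[[k]][i] && cols[[k]][j]) {
        dup <- cols[[k]]
        dup[i] <- FALSE                      # copy without i
        cols[[k]][j] <- FALSE                # original without j
        cols[[length(cols) + 1]] <- dup
      }
    }
    # absorb: drop columns that are strict subsets of another, and
    # duplicates
    keep <- rep(TRUE, length(cols))
    for (a in seq_along(cols)) for (b in seq_along(cols)) {
      if (a == b || !keep[a] || !keep[b]) next
      if (all(cols[[a]] <= cols[[b]]) &&
          (any(cols[[a]] < cols[[b]]) || a > b))
        keep[a] <- FALSE
    }
    cols <- cols[keep]
  }
  # order letters by first member for a tidy display
  cols <- cols[order(vapply(cols, which.max, integer(1)))]
  vapply(seq_len(n), function(i)
    paste(letters[which(vapply(cols, `[`, logical(1), i))],
          collapse = ""), character(1))
}

#' Student's-LSD letter display of treatment cell means
#'
#' Estimated marginal cell means are extracted from the fitted mixed
#' model, all pairwise t comparisons are performed at `alpha` with no
#' multiplicity adjustment (the classical protected-LSD convention),
#' and a connected-letter display is built: cells sharing no letter
#' differ significantly. Means are reported on the model scale and
#' back-transformed to the response scale.
#'
#' @param fit a `"MixedModelFit"` from [fitLMM()].
#' @param specs character vector of factor names defining the cells,
#'   e.g. `c("moisture", "wetting")`.
#' @param alpha comparison-wise significance level.
#' @return data.frame: one row per cell with the factor levels,
#'   `emmean` (model scale), `SE`, `mean_response` (back-transformed),
#'   `letters`.
#' @export
lsdGroups <- function(fit, specs, alpha = 0.05) {
  stopifnot(inherits(fit, "MixedModelFit"))
  emm <- suppressMessages(emmeans::emmeans(
    fit$model, specs = specs,
    lmer.df = if (fit$ddf == "Satterthwaite") "satterthwaite"
              else "kenward-roger"))
  means <- as.data.frame(emm)
  if (nrow(means) < 2) stop("need at least 2 cells to compare")
  prs <- as.data.frame(emmeans::contrast(emm, method = "pairwise",
                                         adjust = "none"))
  labelsOf <- function(df) {
    apply(df[, specs, drop = FALSE], 1, paste, collapse = " ")
  }
  lab <- labelsOf(means)
  n <- length(lab)
  sig <- matrix(FALSE, n, n, dimnames = list(lab, lab))
  for (r in seq_len(nrow(prs))) {
    pair <- strsplit(prs$contrast[r], " - ")[[1]]
    pair <- gsub("[()]", "", pair)
    # emmeans labels combinations as "level1 level2"
    i <- match(pair[1], lab); j <- match(pair[2], lab)
    if (is.na(i) || is.na(j)) next
    sig[i, j] <- sig[j, i] <- prs$p.value[r] < alpha
  }
  means$letters <- .letterDisplay(lab, sig)
  means$mean_response <- fit$inverse(means$emmean)
  means[, c(specs, "emmean", "SE", "mean_response", "letters")]
}

# ---- ratios and correlations ------------------------------------------

#' Treatment-ratio contrasts from a cell-mean summary
#'
#' Computes the ratios of treatment means conventionally quoted for
#' this design: on CO2-C, drought+precipitation vs field+precipitation,
#' vs field+groundwater, and vs drought+groundwater; on CH4-C,
#' drought+groundwater vs field+groundwater. Ratios are rounded to two
#' significant figures.
#'
#' @param means data.frame with columns `moisture`, `wetting`,
#'   `co2_mgC`, `ch4_ugC`; one row per moisture x wetting cell (e.g.
#'   the intact-core columns of a published summary table, or
#'   generator output).
#' @return data.frame with `gas`, `numerator`, `denominator`, `ratio`.
#' @examples
#' tab <- defaultFluxPresets()
#' ratioTable(tab[tab$structure == "intact", ])$ratio  # 4.7 2.4 1.5 8.8
#' @export
ratioTable <- function(means) {
  need <- c("moisture", "wetting", "co2_mgC", "ch4_ugC")
  stopifnot(all(need %in% names(means)))
  cell <- function(m, w, col) {
    v <- means[means$moisture == m & means$wetting == w, col]
    if (length(v) != 1 || !is.finite(v))
      stop("missing or duplicated cell: ", m, " / ", w)
    v
  }
  contrasts <- list(
    list(gas = "co2",
         num = c("drought", "top_precipitation"),
         den = c("field", "top_precipitation")),
    list(gas = "co2",
         num = c("drought", "top_precipitation"),
         den = c("field", "bottom_groundwater")),
    list(gas = "co2",
         num = c("drought", "top_precipitation"),
         den = c("drought", "bottom_groundwater")),
    list(gas = "ch4",
         num = c("drought", "bottom_groundwater"),
         den = c("field", "bottom_groundwater")))
  rows <- lapply(contrasts, function(ct) {
    col <- if (ct$gas == "co2") "co2_mgC" else "ch4_ugC"
    den <- cell(ct$den[1], ct$den[2], col)
    if (den == 0) stop("zero denominator in ratio contrast")
    data.frame(gas = toupper(sub("co2", "CO2-C", sub("ch4", "CH4-C",
                                                     ct$gas))),
               numerator = paste(ct$num, collapse = " + "),
               denominator = paste(ct$den, collapse = " + "),
               ratio = signif(cell(ct$num[1], ct$num[2], col) / den, 2))
  })
  do.call(rbind, rows)
}

#' Correlation with significance test
#'
#' Thin wrapper around [stats::cor.test()] guarding against degenerate
#' input.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @param method `"pearson"` (default), `"spearman"` or `"kendall"`.
#' @return List with `r`, `p`, `n`, `method`.
#' @examples
#' correlate(1:10, 2 * (1:10))$r  # 1
#' @export
correlate <- function(x, y, method = "pearson") {
  stopifnot(length(x) == length(y))
  if (length(x) < 3) stop("need at least 3 paired observations")
  if (sd(x) == 0 || sd(y) == 0)
    stop("zero variance in x or y")
  ct <- cor.test(x, y, method = method)
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x),
       method = method)
}
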