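#' The standard eight-class Van Krevelen scheme
#'
#' Builds the [ClassScheme-class] used throughout: lipids
#' (0 < O/C <= 0.3, 1.5 <= H/C <= 2.5), unsaturated hydrocarbons
#' (0 <= O/C <= 0.125, 0.8 <= H/C < 2.5), proteins
#' (0.3 < O/C <= 0.55, 1.5 <= H/C <= 2.3), amino sugars
#' (0.55 < O/C <= 0.7, 1.5 <= H/C <= 2.2), carbohydrates
#' (0.7 < O/C <= 1.5, 1.5 <= H/C <= 2.5), lignin
#' (0.125 < O/C <= 0.65, 0.8 <= H/C < 1.5), tannins
#' (0.65 < O/C <= 1.1, 0.8 <= H/C < 1.5) and condensed hydrocarbons
#' (0 <= O/C <= 0.95, 0.2 <= H/C < 0.8).
#'
#' The lipid and unsaturated-hydrocarbon boxes overlap for
#' O/C <= 0.125, 1.5 <= H/C < 2.5; the default precedence evaluates the
#' more specific unsaturated-hydrocarbon box first so every point
#' resolves deterministically. The precedence is configurable and is
#' recorded in run manifests.
#'
#' @param precedence character vector ordering the eight class names;
#'   the first containing box wins.
#' @return A [ClassScheme-class].
#' @examples
#' sc <- vanKrevelenScheme()
#' classifyFormulas(oc = 0.5, hc = 1.0, scheme = sc)  # "lignin"
#' @export
vanKrevelenScheme <- function(precedence = c(
    "unsaturated_hydrocarbons", "condensed_hydrocarbons", "lipids",
    "proteins", "amino_sugars", "carbohydrates", "lignin", "tannins")) {
  boxes <- data.frame(
    class = c("lipids", "unsaturated_hydrocarbons", "proteins",
              "amino_sugars", "carbohydrates", "lignin", "tannins",
              "condensed_hydrocarbons"),
    oc_lo = c(0,    0,     0.3,  0.55, 0.7,  0.125, 0.65, 0),
    oc_lo_closed = c(FALSE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE),
    oc_hi = c(0.3,  0.125, 0.55, 0.7,  1.5,  0.65,  1.1,  0.95),
    oc_hi_closed = rep(TRUE, 8),
    hc_lo = c(1.5,  0.8,   1.5,  1.5,  1.5,  0.8,   0.8,  0.2),
    hc_lo_closed = rep(TRUE, 8),
    hc_hi = c(2.5,  2.5,   2.3,  2.2,  2.5,  1.5,   1.5,  0.8),
    hc_hi_closed = c(TRUE, FALSE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  )
  new("ClassScheme", boxes = boxes, precedence = precedence)
}

#' Class names of a scheme, plus "unnamed"
#'
#' @param scheme a [ClassScheme-class].
#' @return Character vector of the box classes in precedence order
#'   followed by `"unnamed"`.
#' @export
classLabels <- function(scheme = vanKrevelenScheme()) {
  c(schemePrecedence(scheme), "unnamed")
}

# membership of (oc, hc) points in one box row, honoring open/closed ends
.inBox <- function(oc, hc, box) {
  lo_oc <- if (box$oc_lo_closed) oc >= box$oc_lo else oc > box$oc_lo
  hi_oc <- if (box$oc_hi_closed) oc <= box$oc_hi else oc < box$oc_hi
  lo_hc <- if (box$hc_lo_closed) hc >= box$hc_lo else hc > box$hc_lo
  hi_hc <- if (box$hc_hi_closed) hc <= box$hc_hi else hc < box$hc_hi
  lo_oc & hi_oc & lo_hc & hi_hc
}

#' Classify formulas into Van Krevelen compound classes
#'
#' Maps (O/C, H/C) points to the first containing box in the scheme's
#' precedence order, or `"unnamed"` when no box contains the point.
#' Boundary open/closed ends are honored exactly: e.g. H/C = 1.5 at
#' O/C = 0.5 is lignin-box-excluded (H/C < 1.5) but protein-box-included.
#'
#' @param oc,hc numeric vectors of O/C and H/C ratios (recycled to common
#'   length).
#' @param scheme a [ClassScheme-class].
#' @return Character vector of class labels.
#' @examples
#' classifyFormulas(c(0.2, 0.5, 1.4), c(1.8, 1.0, 0.9))
#' @export
classifyFormulas <- function(oc, hc, scheme = vanKrevelenScheme()) {
  n <- max(length(oc), length(hc))
  oc <- rep_len(as.numeric(oc), n)
  hc <- rep_len(as.numeric(hc), n)
  out <- rep("unnamed", n)
  boxes <- schemeBoxes(scheme)
  unresolved <- rep(TRUE, n)
  for (cl in schemePrecedence(scheme)) {
    box <- boxes[boxes$class == cl, , drop = FALSE]
    hit <- unresolved & .inBox(oc, hc, box)
    out[hit] <- cl
    unresolved <- unresolved & !hit
  }
  out
}

#' Box membership matrix for a grid of (O/C, H/C) points
#'
#' Returns which raw boxes (ignoring precedence) contain each point; used
#' to audit that the scheme tiles the plane with the single documented
#' lipid/unsaturated-hydrocarbon overlap.
#'
#' @param oc,hc numeric vectors (same length).
#' @param scheme a [ClassScheme-class].
#' @return Logical matrix, one column per box class.
#' @export
boxMembership <- function(oc, hc, scheme = vanKrevelenScheme()) {
  boxes <- schemeBoxes(scheme)
  m <- sapply(seq_len(nrow(boxes)), function(i)
    .inBox(oc, hc, boxes[i, , drop = FALSE]))
  m <- matrix(m, nrow = length(oc))
  colnames(m) <- boxes$class
  m
}

#' Compound-class relative abundance profile of a sample
#'
#' Counts assigned formulas per class (the eight Van Krevelen classes
#' plus unnamed) and normalizes by the total number of assignments, so
#' the nine fractions sum to one. Molecular richness is the number of
#' assigned peaks. Relative abundances are count-based: peak intensities
#' play no role, so the profile is invariant to intensity rescaling.
#'
#' @param assignments data.frame from [assignFormulas()] (needs a
#'   `class` column, or `oc`/`hc` columns from which classes are
#'   computed).
#' @param scheme a [ClassScheme-class].
#' @param sampleId sample identifier carried into the result.
#' @return One-row data.frame: `sample_id`, one column per class label,
#'   and `richness`.
#' @examples
#' a <- data.frame(oc = c(0.2, 0.5, 0.5, 1.4), hc = c(1.8, 1, 1, 0.9))
#' abundanceProfile(a, sampleId = "demo")
#' @export
abundanceProfile <- function(assignments, scheme = vanKrevelenScheme(),
                             sampleId = "sample") {
  if (NROW(assignments) == 0)
    stop("profile undefined for an empty assignment set")
  if (!"class" %in% names(assignments)) {
    if (!all(c("oc", "hc") %in% names(assignments)))
      stop("assignments need a 'class' column or 'oc'/'hc' columns")
    assignments$class <- classifyFormulas(assignments$oc, assignments$hc,
                                          scheme)
  }
  labs <- classLabels(scheme)
  counts <- table(factor(assignments$class, levels = labs))
  fr <- as.numeric(counts) / nrow(assignments)
  out <- data.frame(sample_id = sampleId, t(fr),
                    richness = nrow(assignments),
                    stringsAsFactors = FALSE)
  names(out)[1 + seq_along(labs)] <- labs
  rownames(out) <- NULL
  out
}

#' Assemble per-sample profiles into a SummarizedExperiment
#'
#' Rows are compound classes (assay `"relabund"`), columns are samples;
#' `colData` carries the design factors joined by `sample_id`, plus
#' richness.
#'
#' @param profiles data.frame of row-bound [abundanceProfile()] outputs.
#' @param design optional data.frame with a `sample_id` column of design
#'   factors to attach as column metadata.
#' @param scheme a [ClassScheme-class].
#' @return A [SummarizedExperiment::SummarizedExperiment-class].
#' @export
profilesToSE <- function(profiles, design = NULL,
                         scheme = vanKrevelenScheme()) {
  labs <- classLabels(scheme)
  stopifnot(all(labs %in% names(profiles)))
  m <- t(as.matrix(profiles[, labs, drop = FALSE]))
  colnames(m) <- profiles$sample_id
  cd <- data.frame(sample_id = profiles$sample_id,
                   richness = profiles$richness)
  if (!is.null(design))
    cd <- merge(cd, design, by = "sample_id", sort = FALSE)
  cd <- cd[match(profiles$sample_id, cd$sample_id), , drop = FALSE]
  SummarizedExperiment::SummarizedExperiment(
    assays = list(relabund = m),
    colData = S4Vectors::DataFrame(cd, row.names = profiles$sample_id))
}
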