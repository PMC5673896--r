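#' Read a peak list from delimited text
#'
#' Accepts CSV or TSV with columns `mz` and `intensity` and optionally
#' `snr`; when `snr` is absent it is estimated as intensity over a
#' configured noise floor. Rows failing validation (non-numeric fields,
#' nonpositive m/z) are reported with their line numbers.
#'
#' @param path file path; delimiter inferred from the first line
#'   (tab if present, comma otherwise).
#' @param sampleId sample identifier; defaults to the file name without
#'   extension.
#' @param noiseFloor intensity corresponding to S/N = 1, used only when
#'   the file has no `snr` column.
#' @return A [PeakList-class].
#' @seealso [writePeakList()]
#' @export
readPeakList <- function(path, sampleId = NULL, noiseFloor = 1) {
  if (!file.exists(path)) stop("no such file: ", path)
  first <- readLines(path, n = 1L)
  if (length(first) == 0)
    stop("empty peak-list file: ", path)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  if (nrow(df) == 0)
    stop("peak-list file has a header but no rows: ", path)
  if (!all(c("mz", "intensity") %in% names(df)))
    stop("peak-list file must have 'mz' and 'intensity' columns: ", path)
  mz <- suppressWarnings(as.numeric(df$mz))
  intensity <- suppressWarnings(as.numeric(df$intensity))
  bad <- which(!is.finite(mz) | mz <= 0 | !is.finite(intensity))
  if (length(bad))
    stop("malformed peak rows at line(s) ",
         paste(bad + 1L, collapse = ", "), " of ", path)
  snr <- if ("snr" %in% names(df)) {
    s <- suppressWarnings(as.numeric(df$snr))
    badS <- which(!is.finite(s) | s < 0)
    if (length(badS))
      stop("malformed snr values at line(s) ",
           paste(badS + 1L, collapse = ", "), " of ", path)
    s
  } else intensity / noiseFloor
  if (is.null(sampleId))
    sampleId <- sub("\\.[^.]*$", "", basename(path))
  PeakList(mz = mz, intensity = intensity, snr = snr, sampleId = sampleId)
}

#' Write a peak list as CSV
#'
#' Columns `mz`, `intensity`, `snr`; full double precision is preserved
#' so a write/read cycle is the identity.
#'
#' @param x a [PeakList-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writePeakList <- function(x, path) {
  stopifnot(is(x, "PeakList"))
  df <- peaks(x)
  df$mz <- sprintf("%.10f", df$mz)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Filter peaks by signal-to-noise ratio
#'
#' Retains peaks whose S/N is strictly greater than the threshold
#' (default 7, the conventional cut for formula assignment); order is
#' preserved and an empty result is allowed.
#'
#' @param x a [PeakList-class].
#' @param threshold positive S/N cut; peaks with `snr > threshold` are
#'   kept.
#' @return A filtered [PeakList-class].
#' @examples
#' pl <- PeakList(mz = c(210.1, 300.2), intensity = c(1, 9),
#'                snr = c(7, 7.01))
#' nPeaks(filterSNR(pl))  # 1: S/N exactly 7 is removed
#' @export
filterSNR <- function(x, threshold = 7) {
  stopifnot(is(x, "PeakList"), threshold > 0)
  df <- peaks(x)[peaks(x)$snr > threshold, , drop = FALSE]
  rownames(df) <- NULL
  new("PeakList", peaks = df, polarity = polarity(x),
      sampleId = sampleId(x))
}
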