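#' Multichannel hemoglobin-concentration time series
#'
#' Container for band- or broadband ΔHbO (and optionally ΔHbR) concentration
#' changes in μM, sampled on a regular grid. Sample i is at time
#' `start + (i-1)/fs` seconds.
#'
#' @param hbo Numeric matrix, time x channel, ΔHbO in μM.
#' @param fs Sampling rate in Hz.
#' @param channels Channel labels (default: column names of `hbo`).
#' @param hbr Optional ΔHbR matrix of the same shape.
#' @param markers Optional data frame with columns `time` (s) and `label`.
#' @param start Time of the first sample in seconds (default 0).
#' @param band Optional length-2 band (Hz) the series is limited to; set by
#'   [bandpass_series()].
#' @return An object of class `hemo_series`.
#' @export
hemo_series <- function(hbo, fs, channels = colnames(hbo), hbr = NULL,
                        markers = NULL, start = 0, band = NULL) {
  hbo <- as.matrix(hbo)
  if (!all(is.finite(hbo))) stopf("ΔHbO contains non-finite values")
  assert_scalar_num(fs, "fs", lower = 1e-9)
  if (is.null(channels)) channels <- sprintf("Ch%02d", seq_len(ncol(hbo)))
  if (length(channels) != ncol(hbo)) stopf("channel labels do not match column count")
  colnames(hbo) <- channels
  if (!is.null(hbr)) {
    hbr <- as.matrix(hbr)
    if (!identical(dim(hbr), dim(hbo))) stopf("ΔHbR shape must match ΔHbO")
    colnames(hbr) <- channels
  }
  if (!is.null(markers)) {
    if (!all(c("time", "label") %in% names(markers))) stopf("markers need `time` and `label` columns")
    span <- c(start, start + (nrow(hbo) - 1) / fs)
    if (any(markers$time < span[1] - 1e-9 | markers$time > span[2] + 1e-9)) {
      stopf("marker times fall outside the recorded span")
    }
  }
  structure(list(hbo = hbo, hbr = hbr, fs = fs, channels = channels,
                 markers = markers, start = start, band = band),
            class = "hemo_series")
}

#' @export
print.hemo_series <- function(x, ...) {
  cat(sprintf("hemo_series: %d channels x %d samples @ %.3f Hz (%.1f s)\n",
              ncol(x$hbo), nrow(x$hbo), x$fs, nrow(x$hbo) / x$fs))
  if (!is.null(x$band)) cat(sprintf("  band-limited to %.3f-%.3f Hz\n", x$band[1], x$band[2]))
  if (!is.null(x$markers)) cat(sprintf("  %d markers\n", nrow(x$markers)))
  invisible(x)
}

hemo_times <- function(x) x$start + (seq_len(nrow(x$hbo)) - 1) / x$fs

# Subset a hemo_series to the half-open time interval [from, to], keeping
# absolute time (start field) and in-range markers.
crop_series <- function(x, from, to) {
  t <- hemo_times(x)
  keep <- which(t >= from - 1e-9 & t <= to + 1e-9)
  if (length(keep) < 2L) stopf("requested interval contains fewer than 2 samples")
  mk <- x$markers
  if (!is.null(mk)) mk <- mk[mk$time >= from - 1e-9 & mk$time <= to + 1e-9, , drop = FALSE]
  hemo_series(x$hbo[keep, , drop = FALSE], fs = x$fs, channels = x$channels,
              hbr = if (!is.null(x$hbr)) x$hbr[keep, , drop = FALSE],
              markers = mk, start = t[keep[1]], band = x$band)
}
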