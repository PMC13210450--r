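# Zero-phase Butterworth filtering with odd-symmetric reflection padding.
#
# `band` of length 1 designs a low-pass at that cutoff, length 2 a band-pass.
# The record is extended at both ends by reflecting it (point symmetry about
# the end sample) over 3x the slowest filter time scale (1/lowest cutoff),
# capped at n-1 samples, then filtered forward and backward; the padding is
# discarded. Forward-backward application squares the magnitude response and
# cancels the phase response.
zero_phase_filter <- function(x, fs, band, order = 3) {
  nyq <- fs / 2
  if (any(band <= 0) || any(band >= nyq)) {
    stopf("filter band must lie strictly inside (0, Nyquist = %.4g Hz)", nyq)
  }
  flt <- if (length(band) == 1L) {
    signal::butter(order, band / nyq, type = "low")
  } else {
    if (band[1] >= band[2]) stopf("band edges must be increasing")
    signal::butter(order, band / nyq, type = "pass")
  }
  apply_one <- function(v) {
    n <- length(v)
    # at least 3x the slowest filter time scale AND enough samples for the
    # state transient of the recursion itself to die out
    pad <- min(n - 1L, max(as.integer(round(3 * fs / min(band))), 100L * order))
    vp <- c(2 * v[1] - v[(pad + 1):2],
            v,
            2 * v[n] - v[(n - 1):(n - pad)])
    y <- as.numeric(signal::filter(flt, vp))
    y <- rev(as.numeric(signal::filter(flt, rev(y))))
    y[(pad + 1):(pad + n)]
  }
  if (is.matrix(x)) apply(x, 2, apply_one) else apply_one(x)
}

#' Resample a hemodynamic series
#'
#' Anti-aliased downsampling: the record is low-pass filtered with a
#' zero-phase Butterworth filter (order 6, cutoff `aa_frac` x the target
#' Nyquist) and evaluated on the target grid by cubic-spline interpolation.
#' Marker times are carried over unchanged (they are in seconds). Only
#' downsampling is supported.
#'
#' @param hemo A [hemo_series()].
#' @param target_rate Target rate in Hz (default 2; must be below the
#'   current rate).
#' @param aa_frac Anti-alias cutoff as a fraction of the target Nyquist
#'   (default 0.8).
#' @return A [hemo_series()] at `target_rate`.
#' @export
resample_series <- function(hemo, target_rate = 2, aa_frac = 0.8) {
  stopifnot(inherits(hemo, "hemo_series"))
  if (target_rate >= hemo$fs) stopf("upsampling (%.3f -> %.3f Hz) is not supported", hemo$fs, target_rate)
  t_old <- hemo_times(hemo)
  dur <- t_old[length(t_old)] - t_old[1]
  t_new <- hemo$start + seq(0, floor(dur * target_rate) / target_rate, by = 1 / target_rate)
  cutoff <- aa_frac * target_rate / 2
  rs <- function(m) {
    mf <- zero_phase_filter(m, hemo$fs, band = cutoff, order = 6)
    apply(mf, 2, function(v) stats::spline(t_old, v, xout = t_new)$y)
  }
  hemo_series(rs(hemo$hbo), fs = target_rate, channels = hemo$channels,
              hbr = if (!is.null(hemo$hbr)) rs(hemo$hbr),
              markers = hemo$markers, start = hemo$start, band = hemo$band)
}

#' Zero-phase band-pass filter
#'
#' Third-order Butterworth band-pass (default 0.005-0.05 Hz) applied forward
#' and backward (zero phase distortion, squared magnitude response) with
#' odd-symmetric reflection padding at the record edges. Removes slow drift
#' and DC along with cardiac/respiratory/Mayer-wave components, leaving the
#' low-frequency band used for hemodynamic connectivity.
#'
#' @param hemo A [hemo_series()].
#' @param low,high Band edges in Hz (defaults 0.005 and 0.05).
#' @param order Butterworth order per pass (default 3).
#' @return A [hemo_series()] with the `band` field set.
#' @export
bandpass_series <- function(hemo, low = 0.005, high = 0.05, order = 3) {
  stopifnot(inherits(hemo, "hemo_series"))
  if (!(0 < low && low < high && high < hemo$fs / 2)) {
    stopf("band [%.4g, %.4g] Hz must satisfy 0 < low < high < Nyquist (%.4g Hz)",
          low, high, hemo$fs / 2)
  }
  f <- function(m) zero_phase_filter(m, hemo$fs, band = c(low, high), order = order)
  hemo_series(f(hemo$hbo), fs = hemo$fs, channels = hemo$channels,
              hbr = if (!is.null(hemo$hbr)) f(hemo$hbr),
              markers = hemo$markers, start = hemo$start, band = c(low, high))
}

#' Segment a series into baseline-corrected epochs
#'
#' Cuts one epoch per trial around each task onset, on the half-open window
#' `[window[1], window[2])` relative to onset (124 samples at 2 Hz with the
#' default -1..61 s window); the onset sample is the first sample at or
#' after the marker time. Each epoch/channel is baseline-corrected by
#' subtracting its mean over the samples with relative time in
#' `[baseline[1], baseline[2])`. Trials whose window exceeds the record are
#' dropped and reported in the `dropped` field.
#'
#' @param hemo A [hemo_series()] (typically filtered, 2 Hz).
#' @param schedule A [generate_paradigm()] schedule supplying task onsets
#'   and condition labels.
#' @param window Epoch window in seconds relative to task onset.
#' @param baseline Baseline window in seconds relative to task onset.
#' @param subject Optional subject id stored with the epochs.
#' @return An object of class `epoch_set`: list with `data` (time x channel
#'   x epoch array), `index` (condition, trial, onset, subject), `times`
#'   (relative time grid), `fs`, `channels`, and `dropped`.
#' @export
epoch_and_baseline <- function(hemo, schedule, window = c(-1, 61),
                               baseline = c(-1, 0), subject = NA_character_) {
  stopifnot(inherits(hemo, "hemo_series"), inherits(schedule, "paradigm_schedule"))
  fs <- hemo$fs
  t <- hemo_times(hemo)
  n <- length(t)
  n_win <- as.integer(round((window[2] - window[1]) * fs))
  rel <- window[1] + (seq_len(n_win) - 1) / fs
  bl_idx <- which(rel >= baseline[1] - 1e-9 & rel < baseline[2] - 1e-9)
  if (!length(bl_idx)) stopf("baseline window contains no samples at %.3f Hz", fs)

  tr <- schedule$trials
  keep <- list(); dropped <- list()
  for (i in seq_len(nrow(tr))) {
    onset_idx <- which(t >= tr$task_onset[i] - 1e-9)[1]
    first <- onset_idx + as.integer(round(window[1] * fs))
    last <- first + n_win - 1L
    if (is.na(onset_idx) || first < 1L || last > n) {
      dropped[[length(dropped) + 1L]] <- data.frame(
        condition = tr$condition[i], trial = tr$trial[i], onset = tr$task_onset[i],
        reason = if (is.na(onset_idx) || first < 1L) "insufficient pre-onset data"
                 else "record ends before epoch window",
        stringsAsFactors = FALSE)
      next
    }
    keep[[length(keep) + 1L]] <- list(i = i, first = first)
  }
  if (!length(keep)) stopf("no trial yields a complete epoch window")
  data <- array(NA_real_, c(n_win, length(hemo$channels), length(keep)),
                dimnames = list(NULL, hemo$channels, NULL))
  idx <- do.call(rbind, lapply(seq_along(keep), function(k) {
    i <- keep[[k]]$i
    seg <- hemo$hbo[keep[[k]]$first + seq_len(n_win) - 1L, , drop = FALSE]
    seg <- sweep(seg, 2, colMeans(seg[bl_idx, , drop = FALSE]))
    data[, , k] <<- seg
    data.frame(condition = tr$condition[i], trial = tr$trial[i],
               onset = tr$task_onset[i], subject = subject,
               stringsAsFactors = FALSE)
  }))
  dropped <- if (length(dropped)) do.call(rbind, dropped) else
    data.frame(condition = character(), trial = integer(), onset = numeric(),
               reason = character(), stringsAsFactors = FALSE)
  if (nrow(dropped)) {
    message(sprintf("epoch_and_baseline: dropped %d of %d trials (%s)",
                    nrow(dropped), nrow(tr), paste(unique(dropped$reason), collapse = "; ")))
  }
  structure(list(data = data, index = idx, times = rel, fs = fs,
                 channels = hemo$channels, baseline_window = baseline,
                 dropped = dropped),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("epoch_set: %d epochs x %d channels x %d samples @ %.3f Hz\n",
              dim(x$data)[3], dim(x$data)[2], dim(x$data)[1], x$fs))
  print(table(x$index$condition))
  invisible(x)
}
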