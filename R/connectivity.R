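# Analytic signal via the FFT half-spectrum construction: double the
# positive frequencies, zero the negative ones (DC and Nyquist kept once),
# inverse transform. The angle of the result is the instantaneous phase.
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Instantaneous phase of a band-limited series
#'
#' Computes the analytic-signal angle per channel (Hilbert construction) and
#' trims `edge_trim` seconds at both ends, where the transform's circularity
#' distorts the phase. The input should already be band-limited; a series
#' without a recorded band (see [bandpass_series()]) is accepted with a
#' warning.
#'
#' @param hemo A [hemo_series()].
#' @param edge_trim Seconds discarded at each end (default 50, about one
#'   cycle of the band's lower-middle frequencies).
#' @return Object of class `phase_series`: list with `phase` (time x channel
#'   matrix, radians in (-pi, pi]), `fs`, `channels`, `band`, `edge_trim`.
#' @export
instantaneous_phase <- function(hemo, edge_trim = 50) {
  stopifnot(inherits(hemo, "hemo_series"))
  if (is.null(hemo$band)) {
    warning("input series carries no band annotation; phase is only meaningful for band-limited signals")
  }
  n <- nrow(hemo$hbo)
  trim_n <- as.integer(round(edge_trim * hemo$fs))
  if (n <= 2 * trim_n) {
    stopf("series too short (%d samples) for an edge trim of %g s per end", n, edge_trim)
  }
  ph <- apply(hemo$hbo, 2, function(v) Arg(analytic_signal(v)))
  keep <- (trim_n + 1):(n - trim_n)
  structure(list(phase = ph[keep, , drop = FALSE], fs = hemo$fs,
                 channels = hemo$channels, band = hemo$band,
                 edge_trim = edge_trim),
            class = "phase_series")
}

#' Phase-locking value of two phase series
#'
#' PLV = | (1/N) sum_t exp(i (phi_a(t) - phi_b(t))) |, the modulus of the
#' mean unit phasor of the phase difference; 1 for perfectly locked phases,
#' near 0 for unrelated ones (expected value sqrt(pi)/(2 sqrt(N)) under
#' independent uniform phases).
#'
#' @param phase_a,phase_b Numeric vectors of instantaneous phase (radians),
#'   equal length N >= 2.
#' @return A number in `[0, 1]`.
#' @export
plv <- function(phase_a, phase_b) {
  if (length(phase_a) != length(phase_b)) stopf("phase vectors differ in length")
  if (length(phase_a) < 2L) stopf("at least 2 samples are required")
  Mod(mean(exp(1i * (phase_a - phase_b))))
}

#' Extract the continuous segment of one condition
#'
#' The segment runs from the first trial's intro onset to the last trial's
#' rest end of the given condition: an unbroken span (~10 min with the
#' default 10-trial blocks), as required for meaningful instantaneous phase.
#'
#' @param hemo A [hemo_series()] covering the session.
#' @param schedule The [generate_paradigm()] schedule.
#' @param condition Condition label.
#' @return A cropped [hemo_series()].
#' @export
condition_segment <- function(hemo, schedule, condition) {
  tr <- schedule$trials[schedule$trials$condition == condition, ]
  if (!nrow(tr)) stopf("condition %s not present in the schedule", condition)
  crop_series(hemo, min(tr$intro_onset), max(tr$trial_end))
}

#' Channel-wise PLV connectivity matrix
#'
#' Computes instantaneous phases over one continuous segment and the PLV for
#' every channel pair from the same trimmed span. Segments shorter than
#' `min_segment` seconds (default 400 s, two cycles of the band's lowest
#' frequency) are rejected rather than zero-padded.
#'
#' @param hemo A band-limited [hemo_series()] (one condition segment).
#' @param edge_trim Seconds trimmed per end before the PLV (default 50).
#' @param min_segment Minimum segment duration in seconds (default 400).
#' @return A symmetric `conn_matrix` (channels x channels) with unit
#'   diagonal, values in `[0, 1]`.
#' @export
plv_matrix <- function(hemo, edge_trim = 50, min_segment = 400) {
  stopifnot(inherits(hemo, "hemo_series"))
  dur <- (nrow(hemo$hbo) - 1) / hemo$fs
  if (dur < min_segment) {
    stopf("segment of %.1f s is shorter than the %.0f s minimum for stable phase estimation", dur, min_segment)
  }
  ph <- instantaneous_phase(hemo, edge_trim = edge_trim)
  Z <- exp(1i * ph$phase)
  N <- nrow(Z)
  M <- Mod(t(Conj(Z)) %*% Z) / N
  M <- (M + t(M)) / 2
  diag(M) <- 1
  conn_matrix(M, labels = hemo$channels)
}

#' Connectivity matrix container
#'
#' @param m Symmetric numeric matrix with values in `[0, 1]`.
#' @param labels Node labels (channels or ROIs).
#' @return Matrix of class `conn_matrix`.
#' @export
conn_matrix <- function(m, labels = rownames(m)) {
  m <- as.matrix(m)
  if (nrow(m) != ncol(m)) stopf("connectivity matrix must be square")
  if (max(abs(m - t(m))) > 1e-8) stopf("connectivity matrix must be symmetric")
  if (min(m) < -1e-9 || max(m) > 1 + 1e-9) stopf("connectivity values must lie in [0, 1]")
  if (is.null(labels)) labels <- sprintf("N%02d", seq_len(nrow(m)))
  dimnames(m) <- list(labels, labels)
  class(m) <- c("conn_matrix", class(m))
  m
}

#' Aggregate a channel matrix to ROI level
#'
#' The (A, B) entry (A != B) is the mean PLV over all channel pairs (a in A,
#' b in B). The diagonal is the mean over within-ROI pairs, or 1 for a
#' singleton ROI (the seed ROI4 has one channel); diagonal entries never
#' enter downstream statistics.
#'
#' @param M A 15 x 15 channel `conn_matrix`.
#' @param map An ROI partition from [roi_map()].
#' @return A 7 x 7 `conn_matrix` labeled by ROI.
#' @export
roi_mean_connectivity <- function(M, map = roi_map()) {
  validate_roi_map(map, rownames(M))
  rois <- names(map$channels)
  R <- matrix(NA_real_, length(rois), length(rois), dimnames = list(rois, rois))
  for (a in seq_along(rois)) {
    for (b in seq_along(rois)) {
      cha <- map$channels[[a]]; chb <- map$channels[[b]]
      if (a == b) {
        if (length(cha) == 1L) { R[a, b] <- 1; next }
        block <- M[cha, cha, drop = FALSE]
        R[a, b] <- mean(block[upper.tri(block)])
      } else {
        R[a, b] <- mean(M[cha, chb, drop = FALSE])
      }
    }
  }
  conn_matrix(R, labels = rois)
}

#' Seed-based connectivity profile
#'
#' The six seed connections S1..S6: PLV between the seed ROI (ROI4) and each
#' target ROI in the order ROI1, ROI2, ROI3, ROI5, ROI6, ROI7 (so S5 is
#' ROI6-ROI4, the lower-left to center connection).
#'
#' @param R A 7 x 7 ROI `conn_matrix`.
#' @param map ROI map naming the seed and target order.
#' @return Named numeric vector `S1..S6`.
#' @export
seed_profile <- function(R, map = roi_map()) {
  if (!all(c(map$seed, map$seed_targets) %in% rownames(R))) {
    stopf("matrix labels do not contain the seed ROI set")
  }
  stats::setNames(R[map$seed, map$seed_targets],
                  sprintf("S%d", seq_along(map$seed_targets)))
}

#' Threshold a connectivity matrix into a binary adjacency
#'
#' Edge if and only if PLV strictly exceeds `threshold`; the diagonal is
#' excluded. Intended for visualization of strong connections only — graph
#' metrics are always computed on the full weighted matrix.
#'
#' @param M A `conn_matrix`.
#' @param threshold Threshold in `[0, 1]` (default 0.7).
#' @return Logical adjacency matrix with `FALSE` diagonal.
#' @export
binarize <- function(M, threshold = 0.7) {
  assert_scalar_num(threshold, "threshold", 0, 1)
  A <- unclass(M) > threshold
  diag(A) <- FALSE
  A
}
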