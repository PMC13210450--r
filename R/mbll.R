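#' Default molar extinction coefficients
#'
#' Extinction coefficients of oxy- and deoxyhemoglobin at the two default
#' wavelengths, in cm^-1 per μM (base-10 / decadic convention, values of the
#' order used throughout continuous-wave NIRS). Rows are wavelengths,
#' columns the chromophores.
#'
#' @param wavelengths_nm Wavelength pair (only 780/850 have built-in values).
#' @return 2 x 2 matrix with rownames the wavelengths and colnames
#'   `c("HbO", "HbR")`.
#' @export
extinction_defaults <- function(wavelengths_nm = c(780, 850)) {
  tab <- rbind(`780` = c(HbO = 7.354e-4, HbR = 1.3513e-3),
               `850` = c(HbO = 1.1596e-3, HbR = 7.861e-4))
  key <- as.character(wavelengths_nm)
  if (!all(key %in% rownames(tab))) {
    stopf("no built-in extinction values for wavelengths %s; supply a matrix",
          paste(wavelengths_nm, collapse = "/"))
  }
  tab[key, , drop = FALSE]
}

#' Raw dual-wavelength optical intensity series
#'
#' @param intensity Numeric array, time x channel x wavelength, strictly
#'   positive.
#' @param fs Sampling rate (Hz).
#' @param baseline Channel x wavelength matrix of baseline intensities.
#' @param wavelengths_nm Wavelength pair (nm).
#' @param channels Channel labels.
#' @param markers Optional marker data frame (`time`, `label`).
#' @return Object of class `raw_intensity`.
#' @export
raw_intensity <- function(intensity, fs, baseline, wavelengths_nm = c(780, 850),
                          channels = dimnames(intensity)[[2]], markers = NULL) {
  if (length(dim(intensity)) != 3L || dim(intensity)[3] != 2L) {
    stopf("`intensity` must be a time x channel x 2 array")
  }
  if (any(intensity <= 0)) {
    bad <- which(intensity <= 0, arr.ind = TRUE)[1, ]
    stopf("non-positive intensity at sample %d, channel %d, wavelength %d",
          bad[1], bad[2], bad[3])
  }
  assert_scalar_num(fs, "fs", lower = 1e-9)
  if (is.null(channels)) channels <- sprintf("Ch%02d", seq_len(dim(intensity)[2]))
  structure(list(intensity = intensity, fs = fs, baseline = as.matrix(baseline),
                 wavelengths_nm = wavelengths_nm, channels = channels,
                 markers = markers), class = "raw_intensity")
}

mbll_system <- function(extinction, dpf, distance_cm) {
  extinction <- as.matrix(extinction)
  if (!identical(dim(extinction), c(2L, 2L))) stopf("extinction must be 2 x 2")
  if (abs(det(extinction)) < 1e-15) stopf("extinction matrix is singular")
  if (distance_cm <= 0) stopf("`distance_cm` must be > 0")
  dpf <- rep_len(dpf, 2L)
  # ΔOD(λ) = d * DPF(λ) * [ε_HbO(λ), ε_HbR(λ)] %*% [ΔHbO, ΔHbR]
  diag(distance_cm * dpf) %*% extinction
}

#' Forward modified Beer-Lambert model
#'
#' Maps concentration changes to dual-wavelength optical intensities:
#' ΔOD(λ,t) = (ε_HbO(λ) ΔHbO(t) + ε_HbR(λ) ΔHbR(t)) d DPF(λ) and
#' I(λ,t) = I0(λ) 10^(-ΔOD). This is the exact algebraic inverse of
#' [mbll_invert()]; the pair is used to forward-model synthetic raw
#' recordings and to verify the inversion round-trip.
#'
#' @param hemo A [hemo_series()] carrying ΔHbO and ΔHbR (μM). A missing
#'   ΔHbR is treated as zero.
#' @param dpf Differential pathlength factor per wavelength (default 6, 6).
#' @param extinction 2 x 2 extinction matrix in cm^-1 μM^-1
#'   (default [extinction_defaults()]).
#' @param distance_cm Source-detector distance (default 3 cm).
#' @param baseline Baseline intensity: scalar or channel x wavelength matrix
#'   (default 1).
#' @return A [raw_intensity()] object.
#' @export
forward_mbll <- function(hemo, dpf = c(6, 6), extinction = extinction_defaults(),
                         distance_cm = 3, baseline = 1) {
  stopifnot(inherits(hemo, "hemo_series"))
  A <- mbll_system(extinction, dpf, distance_cm)
  nch <- length(hemo$channels)
  if (!is.matrix(baseline)) {
    baseline <- matrix(baseline, nch, 2)
  }
  hbr <- if (is.null(hemo$hbr)) 0 * hemo$hbo else hemo$hbr
  n <- nrow(hemo$hbo)
  out <- array(NA_real_, c(n, nch, 2),
               dimnames = list(NULL, hemo$channels, rownames(extinction)))
  for (j in seq_len(nch)) {
    od <- cbind(hemo$hbo[, j], hbr[, j]) %*% t(A) # n x 2
    out[, j, 1] <- baseline[j, 1] * 10^(-od[, 1])
    out[, j, 2] <- baseline[j, 2] * 10^(-od[, 2])
  }
  raw_intensity(out, fs = hemo$fs, baseline = baseline,
                wavelengths_nm = as.numeric(rownames(extinction)),
                channels = hemo$channels, markers = hemo$markers)
}

#' Invert the modified Beer-Lambert law
#'
#' Converts dual-wavelength intensities to concentration changes:
#' ΔOD(λ,t) = -log10(I(λ,t) / I0(λ)), then the 2 x 2 linear system with the
#' pathlength-scaled extinction matrix is solved per sample for
#' (ΔHbO, ΔHbR) in μM.
#'
#' @param raw A [raw_intensity()] object.
#' @inheritParams forward_mbll
#' @return A [hemo_series()] with ΔHbO and ΔHbR.
#' @export
mbll_invert <- function(raw, dpf = c(6, 6), extinction = extinction_defaults(),
                        distance_cm = 3) {
  stopifnot(inherits(raw, "raw_intensity"))
  A <- mbll_system(extinction, dpf, distance_cm)
  Ainv <- solve(A)
  nch <- length(raw$channels)
  n <- dim(raw$intensity)[1]
  hbo <- matrix(NA_real_, n, nch, dimnames = list(NULL, raw$channels))
  hbr <- hbo
  for (j in seq_len(nch)) {
    I <- raw$intensity[, j, ]
    if (any(I <= 0)) {
      bad <- which(I <= 0, arr.ind = TRUE)[1, ]
      stopf("non-positive intensity in channel %s at sample %d", raw$channels[j], bad[1])
    }
    od <- -log10(sweep(I, 2, raw$baseline[j, ], "/"))
    conc <- od %*% t(Ainv)
    hbo[, j] <- conc[, 1]
    hbr[, j] <- conc[, 2]
  }
  hemo_series(hbo, fs = raw$fs, channels = raw$channels, hbr = hbr,
              markers = raw$markers)
}
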