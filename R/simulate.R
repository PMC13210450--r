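#' Canonical double-gamma hemodynamic response function
#'
#' Difference of two gamma densities: a positive lobe peaking at `peak`
#' seconds and an undershoot peaking at `undershoot` seconds, scaled by
#' `ratio`. With the defaults (6, 16, 1/6) this is the canonical HRF used
#' throughout task-based hemodynamic modeling.
#'
#' @param t Time grid in seconds (>= 0).
#' @param peak,undershoot Gamma shape parameters (unit scale), i.e. the modes
#'   fall near `peak - 1` and `undershoot - 1` s.
#' @param ratio Undershoot amplitude relative to the main lobe.
#' @return Numeric vector of the same length as `t`.
#' @export
hrf_double_gamma <- function(t, peak = 6, undershoot = 16, ratio = 1 / 6) {
  stats::dgamma(t, shape = peak, scale = 1) -
    ratio * stats::dgamma(t, shape = undershoot, scale = 1)
}

#' Specification of planted phase coupling
#'
#' Ground truth for connectivity-recovery tests: the listed channel pairs
#' share one band-internal oscillator. For a coupled channel, `strength` is
#' the fraction of its band-limited variance contributed by the shared
#' oscillator (the remainder is independent band-limited noise), so
#' strength 1 with zero wideband noise yields a phase-locking value of 1.
#'
#' @param pairs List of length-2 character vectors of channel ids.
#' @param freq_hz Shared oscillator frequency, inside the analysis band.
#' @param strength Coupling strength in `[0, 1]`.
#' @param lags_rad Per-channel phase lag in radians: a single value recycled
#'   over coupled channels, or a named vector.
#' @return A `coupling_spec` list.
#' @export
coupling_spec <- function(pairs = list(), freq_hz = 0.02, strength = 0,
                          lags_rad = 0) {
  assert_scalar_num(strength, "strength", 0, 1)
  assert_scalar_num(freq_hz, "freq_hz", lower = 1e-12)
  structure(list(pairs = pairs, freq_hz = freq_hz, strength = strength,
                 lags_rad = lags_rad), class = "coupling_spec")
}

#' Specification of additive noise components
#'
#' Physiological contaminants are modeled as fixed-frequency sinusoids with
#' per-channel random phase (cardiac ~1 Hz, respiratory ~0.3 Hz, Mayer waves
#' ~0.1 Hz), plus white measurement noise, a slow linear drift, band-limited
#' (0.005-0.05 Hz) background activity, and optional motion spikes
#' (exponentially decaying transients at Poisson times; off by default).
#'
#' @param cardiac_um,respiratory_um,mayer_um Sinusoid amplitudes (μM).
#' @param cardiac_hz,respiratory_hz,mayer_hz Their frequencies (Hz).
#' @param white_sd_um White-noise standard deviation (μM).
#' @param drift_um_per_s Maximum absolute linear drift slope (μM/s); each
#'   channel draws its slope uniformly in ±this value.
#' @param band_sd_um Standard deviation of the band-limited background (μM);
#'   this is the component the coupling model partitions.
#' @param spike_rate_per_min,spike_amp_um Motion-spike rate and amplitude.
#' @return A `noise_spec` list.
#' @export
noise_spec <- function(cardiac_um = 0.2, cardiac_hz = 1.0,
                       respiratory_um = 0.1, respiratory_hz = 0.3,
                       mayer_um = 0.1, mayer_hz = 0.1,
                       white_sd_um = 0.1, drift_um_per_s = 5e-4,
                       band_sd_um = 0.15,
                       spike_rate_per_min = 0, spike_amp_um = 0) {
  vals <- c(cardiac_um, respiratory_um, mayer_um, white_sd_um, band_sd_um,
            spike_rate_per_min, spike_amp_um)
  if (any(vals < 0)) stopf("noise amplitudes must be >= 0")
  if (min(cardiac_hz, respiratory_hz, mayer_hz) <= 0) stopf("noise frequencies must be > 0")
  structure(as.list(environment()), class = "noise_spec")
}

# Band-limited Gaussian noise with standard deviation `sd` (exactly, by
# rescaling the realized sd); zeros when sd == 0.
band_noise <- function(n, fs, band, sd) {
  if (sd == 0) return(numeric(n))
  x <- zero_phase_filter(stats::rnorm(n), fs, band = band, order = 3)
  s <- stats::sd(x)
  if (s == 0) return(numeric(n))
  x * (sd / s)
}

#' Simulate multichannel hemodynamic ground truth
#'
#' Forward model for one recording session: per channel,
#' ΔHbO(t) = amplitude x (HRF ⊗ condition task boxcar) + band-limited
#' background (optionally phase-coupled across channels per `coupling`) +
#' physiological and instrumental noise per `noise`. The session response
#' waveform is normalized so `amplitude` is the peak task response in μM.
#' ΔHbR is emitted as -1/3 of ΔHbO plus small independent noise, as a
#' reference companion only. Identical `(arguments, seed)` give identical
#' output.
#'
#' @param schedule A [generate_paradigm()] schedule.
#' @param layout A [channel_layout()].
#' @param coupling A [coupling_spec()].
#' @param noise A [noise_spec()].
#' @param amplitude Peak ΔHbO task response in μM: a single number, or a
#'   channels x conditions matrix (rownames = channel ids, colnames =
#'   condition labels) to plant condition- or channel-specific effects.
#' @param hrf_params List with `peak`, `undershoot`, `ratio` for
#'   [hrf_double_gamma()].
#' @param fs Sampling rate in Hz (default 8.138, the acquisition rate).
#' @param tail Seconds of recording appended after the last trial so that
#'   the final epoch window fits (default 10).
#' @param seed Integer seed.
#' @return A [hemo_series()] with task-onset markers labeled by condition.
#' @export
simulate_hemodynamics <- function(schedule, layout = channel_layout(),
                                  coupling = coupling_spec(),
                                  noise = noise_spec(),
                                  amplitude = 0.5,
                                  hrf_params = list(peak = 6, undershoot = 16, ratio = 1 / 6),
                                  fs = 8.138, tail = 10, seed = 1) {
  stopifnot(inherits(schedule, "paradigm_schedule"))
  channels <- layout$channel
  band <- c(0.005, 0.05)
  if (coupling$freq_hz <= 0 || coupling$freq_hz >= fs / 2) {
    stopf("coupling frequency %.4f Hz outside (0, Nyquist = %.3f Hz)", coupling$freq_hz, fs / 2)
  }
  coupled_ch <- unique(unlist(coupling$pairs))
  if (length(coupled_ch) && !all(coupled_ch %in% channels)) {
    stopf("coupling references unknown channels: %s",
          paste(setdiff(coupled_ch, channels), collapse = ", "))
  }

  dur <- max(schedule$trials$trial_end) + tail
  n <- floor(dur * fs) + 1L
  t <- (seq_len(n) - 1) / fs

  # condition-specific response regressors, unit peak
  hrf_t <- seq(0, 32, by = 1 / fs)
  h <- hrf_double_gamma(hrf_t, hrf_params$peak, hrf_params$undershoot, hrf_params$ratio)
  conv_box <- function(onsets, duration) {
    box <- numeric(n)
    for (on in onsets) box[t >= on & t < on + duration] <- 1
    y <- stats::convolve(box, rev(h), type = "open")[seq_len(n)]
    y
  }
  unit <- conv_box(0 + schedule$lead_in, schedule$durations$task) # single-trial scale
  peak1 <- max(abs(unit))
  regressors <- lapply(schedule$conditions, function(cond) {
    on <- schedule$trials$task_onset[schedule$trials$condition == cond]
    conv_box(on, schedule$durations$task) / peak1
  })
  names(regressors) <- schedule$conditions

  amp <- amplitude
  if (is.matrix(amp)) {
    if (is.null(rownames(amp)) || is.null(colnames(amp))) stopf("amplitude matrix needs channel rownames and condition colnames")
  } else {
    amp <- matrix(amplitude, nrow = length(channels), ncol = 2,
                  dimnames = list(channels, schedule$conditions))
  }

  lags <- coupling$lags_rad
  if (is.null(names(lags))) lags <- stats::setNames(rep_len(lags, length(coupled_ch)), coupled_ch)

  hbo <- with_seed(seed, {
    shared <- cos(2 * pi * coupling$freq_hz * t) # shared oscillator, phase offsets per channel
    m <- matrix(0, n, length(channels), dimnames = list(NULL, channels))
    for (j in seq_along(channels)) {
      ch <- channels[j]
      resp <- numeric(n)
      for (cond in schedule$conditions) resp <- resp + amp[ch, cond] * regressors[[cond]]
      bg <- band_noise(n, fs, band, noise$band_sd_um)
      if (ch %in% coupled_ch && coupling$strength > 0) {
        osc <- sqrt(2) * noise$band_sd_um *
          cos(2 * pi * coupling$freq_hz * t + lags[[ch]])
        bg <- sqrt(coupling$strength) * osc + sqrt(1 - coupling$strength) * bg
      }
      sino <- function(a, f) if (a > 0) a * sin(2 * pi * f * t + stats::runif(1, 0, 2 * pi)) else 0
      phys <- sino(noise$cardiac_um, noise$cardiac_hz) +
        sino(noise$respiratory_um, noise$respiratory_hz) +
        sino(noise$mayer_um, noise$mayer_hz)
      drift <- if (noise$drift_um_per_s > 0) stats::runif(1, -1, 1) * noise$drift_um_per_s * t else 0
      white <- if (noise$white_sd_um > 0) stats::rnorm(n, sd = noise$white_sd_um) else 0
      spikes <- numeric(n)
      if (noise$spike_rate_per_min > 0 && noise$spike_amp_um > 0) {
        k <- stats::rpois(1, noise$spike_rate_per_min * dur / 60)
        if (k > 0) {
          at <- sort(stats::runif(k, 0, dur))
          for (a in at) {
            idx <- which(t >= a)
            spikes[idx] <- spikes[idx] + noise$spike_amp_um * exp(-(t[idx] - a) / 1.0)
          }
        }
      }
      m[, j] <- resp + bg + phys + drift + white + spikes
    }
    m
  })

  hbr <- -hbo / 3 + with_seed(child_seed(seed, 77L),
                              matrix(stats::rnorm(length(hbo), sd = 0.02), nrow(hbo)))
  colnames(hbr) <- channels
  markers <- data.frame(time = schedule$trials$task_onset,
                        label = schedule$trials$condition,
                        stringsAsFactors = FALSE)
  hemo_series(hbo, fs = fs, channels = channels, hbr = hbr, markers = markers)
}
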