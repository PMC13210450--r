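# Statistic-level cohort generators. These draw per-subject summary
# quantities (connectivity matrices, activation statistics) directly, with
# an exactly specified paired effect size on designated units. They are the
# tool for power / type-I studies of the group-level inference, where the
# controlled quantity is the effect size dz itself rather than any
# signal-level parameter; the full signal chain is exercised separately by
# simulate_hemodynamics() and the preprocessing/connectivity modules.

clamp01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

#' Simulate per-subject ROI connectivity matrices for two conditions
#'
#' Each subject's 7 x 7 PLV matrix is `base` plus a subject-level offset
#' (shared by both conditions, sd `subject_sd`) plus independent edge noise
#' (sd `edge_sd`) per condition, clamped to `[0, 1]`, symmetric, unit
#' diagonal. A planted effect adds `dz * sqrt(2) * edge_sd` to the chosen
#' edge in the first condition only, so the paired effect size of that edge
#' is `dz` in expectation (the paired difference has sd `sqrt(2) * edge_sd`).
#'
#' @param n_subjects Number of subjects (default 44).
#' @param planted `NULL`, or `list(rois = c("ROI4", "ROI6"), dz = 0.45)`.
#' @param base Baseline PLV level (default 0.4).
#' @param subject_sd Between-subject sd of the matrix offset (default 0.05).
#' @param edge_sd Within-subject per-edge, per-condition sd (default 0.05).
#' @param rois Node labels (default the seven ROIs).
#' @param seed Integer seed.
#' @return List with `a` and `b` (node x node x subject arrays, first and
#'   second condition) and `planted`.
#' @export
simulate_plv_cohort <- function(n_subjects = 44, planted = NULL, base = 0.4,
                                subject_sd = 0.05, edge_sd = 0.05,
                                rois = names(roi_map()$channels), seed = 1) {
  n_nodes <- length(rois)
  delta <- 0
  pi_idx <- NULL
  if (!is.null(planted)) {
    if (!all(planted$rois %in% rois)) stopf("planted edge references unknown nodes")
    pi_idx <- match(planted$rois, rois)
    delta <- planted$dz * sqrt(2) * edge_sd
  }
  with_seed(seed, {
    make <- function(off, bump) {
      m <- matrix(0, n_nodes, n_nodes)
      e <- stats::rnorm(n_nodes * (n_nodes - 1) / 2, sd = edge_sd)
      m[upper.tri(m)] <- base + off + e
      m <- m + t(m)
      if (!is.null(pi_idx) && bump != 0) {
        m[pi_idx[1], pi_idx[2]] <- m[pi_idx[1], pi_idx[2]] + bump
        m[pi_idx[2], pi_idx[1]] <- m[pi_idx[1], pi_idx[2]]
      }
      m <- clamp01(m)
      diag(m) <- 1
      m
    }
    a <- array(NA_real_, c(n_nodes, n_nodes, n_subjects), dimnames = list(rois, rois, NULL))
    b <- a
    for (s in seq_len(n_subjects)) {
      off <- stats::rnorm(1, sd = subject_sd)
      a[, , s] <- make(off, delta)
      b[, , s] <- make(off, 0)
    }
    list(a = a, b = b, planted = planted)
  })
}

#' Simulate per-subject channel activation statistics for two conditions
#'
#' Per subject and channel, the activation summary (mean window ΔHbO, μM) is
#' a subject offset plus independent noise per condition; a planted effect
#' adds `dz * sqrt(2) * noise_sd` to one channel in the first condition so
#' its paired effect size is `dz` in expectation.
#'
#' @param n_subjects Number of subjects (default 44).
#' @param planted `NULL`, or `list(channel = "Ch06", dz = 0.5)`.
#' @param base Baseline response level in μM (default 0.3).
#' @param subject_sd Between-subject sd (default 0.15).
#' @param noise_sd Per-condition noise sd (default 0.2).
#' @param channels Channel labels (default Ch01..Ch15).
#' @param seed Integer seed.
#' @return List with `a`, `b` (subject x channel matrices) and `planted`.
#' @export
simulate_activation_cohort <- function(n_subjects = 44, planted = NULL,
                                       base = 0.3, subject_sd = 0.15,
                                       noise_sd = 0.2,
                                       channels = sprintf("Ch%02d", 1:15),
                                       seed = 1) {
  nch <- length(channels)
  delta <- numeric(nch)
  if (!is.null(planted)) {
    j <- match(planted$channel, channels)
    if (is.na(j)) stopf("planted channel not in the layout")
    delta[j] <- planted$dz * sqrt(2) * noise_sd
  }
  with_seed(seed, {
    off <- stats::rnorm(n_subjects, sd = subject_sd)
    a <- base + off + matrix(stats::rnorm(n_subjects * nch, sd = noise_sd), n_subjects) +
      matrix(delta, n_subjects, nch, byrow = TRUE)
    b <- base + off + matrix(stats::rnorm(n_subjects * nch, sd = noise_sd), n_subjects)
    dimnames(a) <- dimnames(b) <- list(NULL, channels)
    list(a = a, b = b, planted = planted)
  })
}
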