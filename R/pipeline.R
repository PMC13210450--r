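#' Pipeline configuration with study defaults
#'
#' All tunables of the simulation and analysis chain, defaulting to the
#' study design: 8.138 Hz acquisition resampled to 2 Hz, 0.005-0.05 Hz
#' third-order zero-phase band-pass, epochs -1..61 s with -1..0 s baseline,
#' 10 trials per condition (0.5 s intro, 24 s task as 3 x 8 s screens, 35 s
#' rest), 3 cm optode separation, FDR level q = 0.05, visualization
#' threshold 0.7.
#'
#' @param n_subjects Simulated cohort size (default 44).
#' @param n_trials Trials per condition (default 10).
#' @param fs Acquisition rate, Hz (default 8.138).
#' @param target_rate Analysis rate after resampling, Hz (default 2).
#' @param band Band-pass edges, Hz (default 0.005, 0.05).
#' @param filter_order Butterworth order (default 3).
#' @param epoch_window,baseline_window Epoch and baseline windows, s.
#' @param activation_window Activation summary window, s (default 0-24).
#' @param edge_trim Hilbert edge trim, s (default 50).
#' @param min_segment Minimum connectivity segment, s (default 400).
#' @param plv_threshold Binary-map threshold (default 0.7).
#' @param q FDR level (default 0.05).
#' @param distance_cm,dpf,wavelengths,extinction Optics constants.
#' @param amplitude Peak response amplitude in μM (scalar or channel x
#'   condition matrix).
#' @param coupling,noise,behavior Component specs.
#' @param seed Master seed; all per-subject seeds derive from it.
#' @param outdir Output directory (`NULL` = no files written).
#' @return A validated `fnirs_config` list.
#' @export
fnirs_config <- function(n_subjects = 44, n_trials = 10, fs = 8.138,
                         target_rate = 2, band = c(0.005, 0.05),
                         filter_order = 3, epoch_window = c(-1, 61),
                         baseline_window = c(-1, 0),
                         activation_window = c(0, 24),
                         edge_trim = 50, min_segment = 400,
                         plv_threshold = 0.7, q = 0.05,
                         distance_cm = 3, dpf = c(6, 6),
                         wavelengths = c(780, 850),
                         extinction = extinction_defaults(),
                         amplitude = 0.5,
                         coupling = coupling_spec(),
                         noise = noise_spec(),
                         behavior = behavior_effect_spec(),
                         seed = 1, outdir = NULL) {
  cfg <- structure(as.list(environment()), class = "fnirs_config")
  validate_config(cfg)
}

validate_config <- function(cfg) {
  if (is.null(cfg$extinction)) stopf("config error: extinction table is required")
  ext <- as.matrix(cfg$extinction)
  if (!identical(dim(ext), c(2L, 2L)) || abs(det(ext)) < 1e-15) {
    stopf("config error: extinction must be an invertible 2 x 2 matrix")
  }
  if (cfg$n_subjects < 1) stopf("config error: n_subjects must be >= 1")
  if (!(0 < cfg$band[1] && cfg$band[1] < cfg$band[2] && cfg$band[2] < cfg$target_rate / 2)) {
    stopf("config error: band must satisfy 0 < low < high < target Nyquist")
  }
  if (cfg$target_rate >= cfg$fs) stopf("config error: target_rate must be below fs")
  if (cfg$q <= 0 || cfg$q >= 1) stopf("config error: q must be in (0, 1)")
  invisible(cfg)
}

process_subject <- function(cfg, subj_seed, subject) {
  schedule <- generate_paradigm(cfg$n_trials, order_seed = subj_seed)
  layout <- channel_layout(cfg$distance_cm, cfg$wavelengths)
  truth <- simulate_hemodynamics(schedule, layout, cfg$coupling, cfg$noise,
                                 amplitude = cfg$amplitude, fs = cfg$fs,
                                 seed = subj_seed)
  raw <- forward_mbll(truth, cfg$dpf, cfg$extinction, cfg$distance_cm)
  hemo <- mbll_invert(raw, cfg$dpf, cfg$extinction, cfg$distance_cm)
  hemo <- resample_series(hemo, cfg$target_rate)
  filt <- bandpass_series(hemo, cfg$band[1], cfg$band[2], cfg$filter_order)
  epochs <- suppressMessages(
    epoch_and_baseline(filt, schedule, cfg$epoch_window, cfg$baseline_window,
                       subject = subject))
  conn <- lapply(schedule$conditions, function(cond) {
    seg <- condition_segment(filt, schedule, cond)
    M <- plv_matrix(seg, edge_trim = cfg$edge_trim, min_segment = cfg$min_segment)
    R <- roi_mean_connectivity(M)
    list(channel = M, roi = R, seed = seed_profile(R),
         network = network_summary(R), binary = binarize(M, cfg$plv_threshold))
  })
  names(conn) <- schedule$conditions
  list(schedule = schedule, epochs = epochs, connectivity = conn)
}

#' Run the full simulation-and-analysis pipeline
#'
#' Per subject: simulate ground-truth hemodynamics, forward-model raw
#' intensities, invert the Beer-Lambert model, resample, band-pass, epoch,
#' and compute per-condition channel/ROI PLV matrices, seed profiles, and
#' network metrics. At group level: channel activation contrast (FDR over 15
#' channels), ROI-pair and seed connectivity contrasts, network-metric
#' contrasts, and behavioral contrasts on a simulated cohort log. Identical
#' configs (including seed) reproduce all outputs exactly.
#'
#' @param cfg An [fnirs_config()].
#' @return List with `subjects` (per-subject results), `group` (contrast
#'   tables), `behavior` (RT and low-price contrasts), and `manifest`
#'   (config hash, seed, package version). If `cfg$outdir` is set, tables
#'   and the manifest are written there.
#' @export
run_pipeline <- function(cfg = fnirs_config()) {
  validate_config(cfg)
  subjects <- sprintf("S%02d", seq_len(cfg$n_subjects))
  per_subj <- lapply(seq_len(cfg$n_subjects), function(s) {
    process_subject(cfg, child_seed(cfg$seed, s), subjects[s])
  })
  names(per_subj) <- subjects

  conds <- per_subj[[1]]$schedule$conditions
  arr_of <- function(level) {
    lapply(stats::setNames(conds, conds), function(cond) {
      simplify2array(lapply(per_subj, function(ps) unclass(ps$connectivity[[cond]][[level]])))
    })
  }
  roi_arr <- arr_of("roi")
  activation <- channel_activation_contrast(lapply(per_subj, `[[`, "epochs"),
                                            conditions = conds,
                                            window = cfg$activation_window, q = cfg$q)
  conn_roi <- connectivity_contrast(roi_arr[[1]], roi_arr[[2]], level = "edge", q = cfg$q)
  conn_seed <- connectivity_contrast(roi_arr[[1]], roi_arr[[2]], level = "seed", q = cfg$q)
  metrics <- network_metric_contrast(roi_arr[[1]], roi_arr[[2]], q = cfg$q)

  log <- simulate_behavior_cohort(cfg$n_subjects, effects = cfg$behavior,
                                  seed = child_seed(cfg$seed, 900001L))
  behav <- list(rt = rt_contrast(log, conds), low_price = low_price_contrast(log, conds))

  manifest <- list(package = "fnirsplv",
                   version = as.character(utils::packageVersion("fnirsplv")),
                   seed = cfg$seed, n_subjects = cfg$n_subjects,
                   config_hash = config_hash(cfg))
  out <- list(subjects = per_subj,
              group = list(activation = activation, roi_pairs = conn_roi,
                           seed = conn_seed, network = metrics),
              behavior = behav, behavior_log = log, manifest = manifest)
  if (!is.null(cfg$outdir)) write_pipeline_outputs(out, cfg)
  out
}

config_hash <- function(cfg) {
  cfg$outdir <- NULL
  tmp <- tempfile(fileext = ".txt")
  on.exit(unlink(tmp))
  writeLines(utils::capture.output(utils::str(cfg, digits.d = 15, vec.len = 1e6)), tmp)
  unname(tools::md5sum(tmp))
}

write_pipeline_outputs <- function(out, cfg) {
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(cfg$outdir, f)
  wt <- function(tab, f) utils::write.table(tab, p(f), sep = "\t", row.names = FALSE, quote = FALSE)
  wt(out$group$activation, "activation_contrast.tsv")
  wt(out$group$roi_pairs, "roi_pair_contrast.tsv")
  wt(out$group$seed, "seed_contrast.tsv")
  wt(out$group$network$nodal, "network_nodal_contrast.tsv")
  wt(out$group$network$global, "network_global_contrast.tsv")
  wt(out$behavior$rt$per_subject, "behavior_rt_per_subject.tsv")
  wt(out$behavior$low_price$summary, "behavior_low_price_summary.tsv")
  write_behavior_log(out$behavior_log, p("behavior_log.tsv"))
  conds <- out$subjects[[1]]$schedule$conditions
  for (cond in conds) {
    avg <- Reduce(`+`, lapply(out$subjects, function(ps) unclass(ps$connectivity[[cond]]$roi))) /
      length(out$subjects)
    write_conn_matrix(conn_matrix(avg), p(sprintf("roi_plv_mean_%s.tsv", cond)))
  }
  jsonlite::write_json(out$manifest, p("manifest.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(out)
}
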