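#' Generate a block-design task schedule
#'
#' Builds the two-condition (OOC: other-oriented consumption; SOC:
#' self-oriented consumption) block paradigm. Each trial is an introduction
#' (0.5 s), a task period (24 s, three consecutive 8 s stimulus screens, one
#' product selection per screen), and a rest period (35 s). Conditions are
#' presented as contiguous blocks whose order is drawn reproducibly from
#' `order_seed` (counterbalancing across subjects is obtained by varying the
#' seed). With the default 10 trials per condition a condition block spans
#' 10 x 59.5 s = 595 s and yields 30 selection events.
#'
#' @param n_trials_per_condition Trials per condition (>= 1; default 10).
#' @param order_seed Integer seed controlling which condition comes first.
#' @param lead_in Seconds of recording before the first trial (default 5).
#' @param conditions Condition labels (default `c("OOC", "SOC")`).
#' @param intro,task,rest Durations in seconds (defaults 0.5, 24, 35).
#' @param n_screens Stimulus screens per trial (default 3, 8 s each).
#' @return An object of class `paradigm_schedule`: a list with `trials`
#'   (condition, trial, intro/task/rest onsets, trial_end), `screens`
#'   (condition, trial, screen, onset, duration), durations, the realized
#'   `condition_order`, and `lead_in`.
#' @export
generate_paradigm <- function(n_trials_per_condition = 10, order_seed = 1,
                              lead_in = 5, conditions = c("OOC", "SOC"),
                              intro = 0.5, task = 24, rest = 35, n_screens = 3) {
  if (!is.numeric(n_trials_per_condition) || length(n_trials_per_condition) != 1L ||
      n_trials_per_condition < 1 || n_trials_per_condition != round(n_trials_per_condition)) {
    stopf("`n_trials_per_condition` must be a positive integer")
  }
  n <- as.integer(n_trials_per_condition)
  if (length(conditions) != 2L) stopf("exactly two condition labels are required")
  screen_dur <- task / n_screens
  trial_dur <- intro + task + rest

  order <- with_seed(order_seed, sample(conditions))
  trials <- do.call(rbind, lapply(seq_along(order), function(b) {
    t0 <- lead_in + (b - 1) * n * trial_dur
    intro_onset <- t0 + (seq_len(n) - 1) * trial_dur
    data.frame(
      condition = order[b], trial = seq_len(n),
      intro_onset = intro_onset,
      task_onset = intro_onset + intro,
      rest_onset = intro_onset + intro + task,
      trial_end = intro_onset + trial_dur,
      stringsAsFactors = FALSE
    )
  }))
  screens <- do.call(rbind, lapply(seq_len(nrow(trials)), function(i) {
    data.frame(
      condition = trials$condition[i], trial = trials$trial[i],
      screen = seq_len(n_screens),
      onset = trials$task_onset[i] + (seq_len(n_screens) - 1) * screen_dur,
      duration = screen_dur, stringsAsFactors = FALSE
    )
  }))
  out <- structure(list(
    trials = trials, screens = screens,
    durations = list(intro = intro, task = task, rest = rest,
                     screen = screen_dur, trial = trial_dur),
    n_trials = n, n_screens = n_screens,
    conditions = conditions, condition_order = order, lead_in = lead_in
  ), class = "paradigm_schedule")
  validate_paradigm(out)
}

validate_paradigm <- function(x) {
  tr <- x$trials
  for (cond in x$conditions) {
    tc <- tr[tr$condition == cond, ]
    if (nrow(tc) != x$n_trials) stopf("condition %s has %d trials, expected %d", cond, nrow(tc), x$n_trials)
    span <- max(tc$trial_end) - min(tc$intro_onset)
    if (abs(span - x$n_trials * x$durations$trial) > 1e-9) {
      stopf("condition %s block span %.3f s != %d x %.1f s", cond, span, x$n_trials, x$durations$trial)
    }
  }
  o <- order(tr$intro_onset)
  if (any(diff(tr$intro_onset[o]) < x$durations$trial - 1e-9)) stopf("trials overlap")
  invisible(x)
}

#' Number of selection events per condition in a schedule
#'
#' @param schedule A `paradigm_schedule`.
#' @return Named integer vector of screen/selection counts per condition.
#' @export
selection_counts <- function(schedule) {
  stopifnot(inherits(schedule, "paradigm_schedule"))
  tab <- table(schedule$screens$condition)
  stats::setNames(as.integer(tab), names(tab))
}

#' @export
print.paradigm_schedule <- function(x, ...) {
  cat(sprintf("Block paradigm: %d trials/condition, order %s\n",
              x$n_trials, paste(x$condition_order, collapse = " -> ")))
  cat(sprintf("  trial = %.1f s intro + %.0f s task (%d x %.0f s screens) + %.0f s rest\n",
              x$durations$intro, x$durations$task, x$n_screens,
              x$durations$screen, x$durations$rest))
  cat(sprintf("  session span %.1f s (lead-in %.1f s)\n",
              max(x$trials$trial_end), x$lead_in))
  invisible(x)
}
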