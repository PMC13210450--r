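#' Behavioral effect specification
#'
#' Generating distribution of the selection log: per-condition response-time
#' mean/sd (ms) and probability of choosing the lower-priced option. The
#' default low-price probabilities follow the observed selection frequencies
#' (7/30 in OOC, 22.97/30 in SOC); default RT means are equal (the group
#' mean RT difference is null), with between-subject variation in the
#' condition RT difference supplied by `rt_diff_subject_sd` so individual
#' subjects can show sizeable differences of either sign.
#'
#' @param rt_mean_ms Named per-condition RT means (ms).
#' @param rt_sd_ms Named per-condition RT sds (ms); > 0.
#' @param low_price_prob Named per-condition probabilities in `[0, 1]`.
#' @param rt_diff_subject_sd Between-subject sd (ms) of the OOC-SOC RT
#'   shift used by [simulate_behavior_cohort()].
#' @return A `behavior_effect_spec` list.
#' @export
behavior_effect_spec <- function(rt_mean_ms = c(OOC = 3500, SOC = 3500),
                                 rt_sd_ms = c(OOC = 1200, SOC = 1200),
                                 low_price_prob = c(OOC = 7 / 30, SOC = 22.97 / 30),
                                 rt_diff_subject_sd = 900) {
  if (any(rt_sd_ms <= 0)) stopf("RT standard deviations must be > 0")
  if (any(low_price_prob < 0 | low_price_prob > 1)) stopf("probabilities must lie in [0, 1]")
  structure(list(rt_mean_ms = rt_mean_ms, rt_sd_ms = rt_sd_ms,
                 low_price_prob = low_price_prob,
                 rt_diff_subject_sd = rt_diff_subject_sd),
            class = "behavior_effect_spec")
}

rtruncnorm_rt <- function(n, mean, sd, upper = 8000) {
  out <- stats::rnorm(n, mean, sd)
  bad <- which(out <= 0 | out > upper)
  while (length(bad)) {
    out[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[out[bad] <= 0 | out[bad] > upper]
  }
  out
}

#' Simulate one subject's selection log
#'
#' One record per selection event (trial x screen) of the schedule: response
#' time drawn from a normal truncated to (0, 8000] ms (the 8 s screen
#' duration), chosen option, and its price tier (low with the condition's
#' probability; two of the four on-screen options are low-priced).
#'
#' @param schedule A [generate_paradigm()] schedule.
#' @param effects A [behavior_effect_spec()].
#' @param seed Integer seed.
#' @param subject Subject id stored in the records.
#' @param rt_shift_ms Named per-condition additive RT shift (subject-level
#'   heterogeneity; default 0).
#' @return Data frame: `subject`, `condition`, `trial`, `screen`, `rt_ms`,
#'   `option`, `price_tier`, `packaged`.
#' @export
simulate_behavior <- function(schedule, effects = behavior_effect_spec(),
                              seed = 1, subject = "S01",
                              rt_shift_ms = c(OOC = 0, SOC = 0)) {
  stopifnot(inherits(schedule, "paradigm_schedule"))
  sc <- schedule$screens
  with_seed(seed, {
    rt <- numeric(nrow(sc)); tier <- character(nrow(sc)); opt <- integer(nrow(sc))
    for (cond in schedule$conditions) {
      k <- which(sc$condition == cond)
      mu <- effects$rt_mean_ms[[cond]] + (rt_shift_ms[[cond]] %||% 0)
      rt[k] <- rtruncnorm_rt(length(k), mu, effects$rt_sd_ms[[cond]],
                             upper = schedule$durations$screen * 1000)
      low <- stats::runif(length(k)) < effects$low_price_prob[[cond]]
      tier[k] <- ifelse(low, "low", "high")
      # options 1-2 are the non-packed (lower-priced) pair, 3-4 the packed pair
      opt[k] <- ifelse(low, sample(1:2, length(k), replace = TRUE),
                       sample(3:4, length(k), replace = TRUE))
    }
    data.frame(subject = subject, condition = sc$condition, trial = sc$trial,
               screen = sc$screen, rt_ms = rt, option = opt, price_tier = tier,
               packaged = tier == "high", stringsAsFactors = FALSE)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate a cohort of selection logs
#'
#' Each subject gets an individual OOC-vs-SOC RT shift drawn from
#' N(0, `effects$rt_diff_subject_sd`), applied with opposite signs to the
#' two conditions, and an independently seeded selection log.
#'
#' @param n_subjects Number of subjects (default 44).
#' @param schedule Schedule shared by all subjects (condition order is
#'   re-drawn per subject for counterbalancing).
#' @param effects A [behavior_effect_spec()].
#' @param seed Integer seed.
#' @return Data frame of all subjects' records.
#' @export
simulate_behavior_cohort <- function(n_subjects = 44, schedule = NULL,
                                     effects = behavior_effect_spec(), seed = 1) {
  shifts <- with_seed(seed, stats::rnorm(n_subjects, 0, effects$rt_diff_subject_sd))
  out <- lapply(seq_len(n_subjects), function(s) {
    sch <- if (is.null(schedule)) generate_paradigm(order_seed = child_seed(seed, 1000L + s)) else schedule
    simulate_behavior(sch, effects, seed = child_seed(seed, s),
                      subject = sprintf("S%02d", s),
                      rt_shift_ms = c(OOC = shifts[s] / 2, SOC = -shifts[s] / 2))
  })
  do.call(rbind, out)
}

#' Response-time contrast
#'
#' Per subject, a two-sample (Welch) t-test compares that subject's OOC
#' selection RTs against the SOC ones (30 vs 30 with the standard schedule).
#' At group level, subject mean RTs per condition are compared with a paired
#' t-test.
#'
#' @param records Selection log, as from [simulate_behavior_cohort()].
#' @param conditions Length-2 condition labels (contrast is first - second).
#' @param alpha Per-subject significance level (default 0.05).
#' @return List with `per_subject` (subject, mean RTs, difference, t, p,
#'   significant) and `group` (one-row paired test on subject means).
#' @export
rt_contrast <- function(records, conditions = c("OOC", "SOC"), alpha = 0.05) {
  subjects <- unique(records$subject)
  rows <- lapply(subjects, function(s) {
    a <- records$rt_ms[records$subject == s & records$condition == conditions[1]]
    b <- records$rt_ms[records$subject == s & records$condition == conditions[2]]
    if (length(a) < 2 || length(b) < 2) {
      message(sprintf("subject %s skipped: fewer than 2 RTs in a condition", s))
      return(NULL)
    }
    if (stats::sd(c(a, b)) == 0) {
      tval <- 0; pval <- 1 # constant data: no evidence of a difference
    } else {
      tt <- stats::t.test(a, b)
      tval <- unname(tt$statistic); pval <- tt$p.value
    }
    data.frame(subject = s, mean_a = mean(a), mean_b = mean(b),
               rt_diff = mean(a) - mean(b), t = tval,
               p = pval, significant = pval < alpha,
               stringsAsFactors = FALSE)
  })
  per_subject <- do.call(rbind, rows)
  names(per_subject)[2:3] <- paste0("mean_", conditions)
  group <- if (nrow(per_subject) >= 2) {
    paired_ttest(per_subject[[2]], per_subject[[3]])
  } # group-level test undefined for a single subject
  list(per_subject = per_subject, group = group)
}

#' Low-price selection-frequency contrast
#'
#' Counts each subject's low-price selections per condition (0..30 with the
#' standard schedule) and compares conditions. `mode = "subject"` (primary):
#' paired t-test across subjects on the counts. `mode = "slot"`: for each of
#' the 30 selection slots (trial x screen), the across-subject selection
#' frequency is computed per condition and the 30 slot values are compared
#' with a paired t-test (df = 29 with the standard schedule) — provided for
#' comparability with selection-slot-level reporting.
#'
#' @param records Selection log with a `price_tier` column.
#' @param conditions Length-2 condition labels.
#' @param mode `"subject"` or `"slot"`.
#' @return List with `summary` (per condition: n_selections, mean, sd,
#'   ratio = mean / n_selections x 100), `counts` (subject x condition), and
#'   `test` (one-row paired test).
#' @export
low_price_contrast <- function(records, conditions = c("OOC", "SOC"),
                               mode = c("subject", "slot")) {
  mode <- match.arg(mode)
  if (any(!records$price_tier %in% c("low", "high"))) stopf("unlabeled price tier in records")
  subjects <- unique(records$subject)
  counts <- vapply(conditions, function(cond) {
    vapply(subjects, function(s) {
      sum(records$price_tier == "low" & records$subject == s & records$condition == cond)
    }, numeric(1))
  }, numeric(length(subjects)))
  counts <- matrix(counts, ncol = 2, dimnames = list(subjects, conditions))
  n_sel <- max(vapply(conditions, function(cond)
    max(table(records$subject[records$condition == cond])), numeric(1)))
  summary <- data.frame(
    condition = conditions, n_selections = n_sel,
    mean = colMeans(counts), sd = apply(counts, 2, stats::sd),
    ratio = colMeans(counts) / n_sel * 100, row.names = NULL
  )
  test <- if (mode == "subject") {
    if (nrow(counts) >= 2) paired_ttest(counts[, 1], counts[, 2])
  } else {
    slot_freq <- vapply(conditions, function(cond) {
      r <- records[records$condition == cond, ]
      agg <- stats::aggregate(r$price_tier == "low",
                              by = list(trial = r$trial, screen = r$screen), FUN = mean)
      agg <- agg[order(agg$trial, agg$screen), ]
      agg$x
    }, numeric(schedule_slots(records, conditions[1])))
    paired_ttest(slot_freq[, 1], slot_freq[, 2])
  }
  list(summary = summary, counts = counts, test = test, mode = mode)
}

schedule_slots <- function(records, condition) {
  r <- records[records$condition == condition, ]
  nrow(unique(r[, c("trial", "screen")]))
}
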