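#' Paired t-test with paired effect size
#'
#' Two-tailed paired t-test on within-subject differences, reporting the
#' paired Cohen's d (dz = mean(diff) / sd(diff)). Zero-variance differences
#' are degenerate: by convention they report p = 1, t = 0, dz = 0 with a
#' warning, so that identical conditions can never be declared significant.
#'
#' @param x,y Per-subject values under the two conditions, paired by
#'   position; equal length n >= 2.
#' @return One-row data frame: `n`, `t`, `df`, `p`, `dz`, `degenerate`.
#' @export
paired_ttest <- function(x, y) {
  if (length(x) != length(y)) stopf("paired samples differ in length")
  n <- length(x)
  if (n < 2) stopf("paired t-test needs at least 2 pairs")
  d <- x - y
  if (stats::sd(d) == 0) {
    warning("zero-variance differences: degenerate paired test, reporting p = 1")
    return(data.frame(n = n, t = 0, df = n - 1L, p = 1, dz = 0, degenerate = TRUE))
  }
  tt <- stats::t.test(x, y, paired = TRUE)
  data.frame(n = n, t = unname(tt$statistic), df = as.integer(unname(tt$parameter)),
             p = tt$p.value, dz = mean(d) / stats::sd(d), degenerate = FALSE)
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up FDR control: adjusted p_(k) = min_{j >= k} ( m p_(j) / j ),
#' capped at 1. The rejection mask is `adjusted < q` (strict).
#'
#' @param p Vector of raw p-values in `[0, 1]`.
#' @param q FDR level (default 0.05).
#' @return Data frame with `p`, `p_adj`, `significant`, in input order.
#' @export
bh_fdr <- function(p, q = 0.05) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) stopf("p-values must lie in [0, 1]")
  assert_scalar_num(q, "q", 0, 1)
  adj <- stats::p.adjust(p, method = "BH")
  data.frame(p = p, p_adj = adj, significant = adj < q)
}

contrast_table <- function(units, rows, q, family) {
  tab <- do.call(rbind, rows)
  tab <- cbind(data.frame(unit = units, stringsAsFactors = FALSE), tab)
  fdr <- bh_fdr(tab$p, q = q)
  tab$p_adj <- fdr$p_adj
  tab$significant <- fdr$significant
  attr(tab, "family") <- family
  attr(tab, "m") <- nrow(tab)
  attr(tab, "q") <- q
  tab
}

#' Channel-wise activation contrast across subjects
#'
#' Per subject, channel, and condition the activation statistic is the mean
#' baseline-corrected ΔHbO over the summary window (default the 0-24 s task
#' period), averaged across that condition's trials. Channels are then
#' compared between conditions with a paired t-test across subjects and
#' BH-FDR corrected over the channel family.
#'
#' @param epoch_sets List of [epoch_and_baseline()] results, one per
#'   subject, each containing both conditions.
#' @param conditions Length-2 condition labels; the contrast is
#'   `conditions[1] - conditions[2]`.
#' @param window Summary window in seconds relative to task onset.
#' @param q FDR level over the channel family (default 0.05).
#' @return Contrast table: one row per channel with `t`, `df`, `p`, `dz`,
#'   `p_adj`, `significant`.
#' @export
channel_activation_contrast <- function(epoch_sets, conditions = c("OOC", "SOC"),
                                        window = c(0, 24), q = 0.05) {
  stats_one <- function(es) {
    sel <- es$times >= window[1] - 1e-9 & es$times < window[2] - 1e-9
    vapply(conditions, function(cond) {
      k <- which(es$index$condition == cond)
      if (!length(k)) return(rep(NA_real_, length(es$channels)))
      colMeans(t(apply(es$data[sel, , k, drop = FALSE], c(2, 3), mean)))
    }, numeric(length(epoch_sets[[1]]$channels)))
  }
  per_subj <- lapply(epoch_sets, stats_one) # each: channels x 2
  complete <- vapply(per_subj, function(m) all(is.finite(m)), logical(1))
  if (any(!complete)) {
    message(sprintf("excluding %d subject(s) missing a condition", sum(!complete)))
    per_subj <- per_subj[complete]
  }
  if (length(per_subj) < 2) stopf("need at least 2 subjects with both conditions")
  channels <- epoch_sets[[which(complete)[1]]]$channels
  rows <- lapply(seq_along(channels), function(j) {
    a <- vapply(per_subj, function(m) m[j, 1], numeric(1))
    b <- vapply(per_subj, function(m) m[j, 2], numeric(1))
    suppressWarnings(paired_ttest(a, b))
  })
  contrast_table(channels, rows, q, family = "channels")
}

edge_labels <- function(labels) {
  idx <- which(upper.tri(diag(length(labels))), arr.ind = TRUE)
  sprintf("%s-%s", labels[idx[, 1]], labels[idx[, 2]])
}

#' Connectivity contrast between conditions
#'
#' Paired t-test per connection across subjects, with BH-FDR within the
#' declared family: all channel or ROI pairs (`level = "edge"`: 105 channel
#' pairs or 21 ROI pairs for the standard montage), or the six seed
#' connections S1..S6 (`level = "seed"`, 7 x 7 ROI matrices required).
#'
#' @param a,b Per-condition connectivity: node x node x subject arrays (or
#'   lists of matrices) with identical node labels and subject order.
#' @param level `"edge"` or `"seed"`.
#' @param map ROI map (used for `level = "seed"`).
#' @param q FDR level (default 0.05).
#' @return Contrast table with one row per connection.
#' @export
connectivity_contrast <- function(a, b, level = c("edge", "seed"),
                                  map = roi_map(), q = 0.05) {
  level <- match.arg(level)
  as_arr <- function(x) if (is.list(x)) simplify2array(x) else x
  a <- as_arr(a); b <- as_arr(b)
  if (!identical(dim(a), dim(b))) stopf("condition arrays differ in shape")
  if (!identical(dimnames(a)[[1]], dimnames(b)[[1]])) stopf("node labels differ between conditions")
  labels <- dimnames(a)[[1]]
  n_sub <- dim(a)[3]
  if (level == "seed") {
    sa <- vapply(seq_len(n_sub), function(s) seed_profile(conn_matrix(a[, , s], labels), map), numeric(6))
    sb <- vapply(seq_len(n_sub), function(s) seed_profile(conn_matrix(b[, , s], labels), map), numeric(6))
    units <- rownames(sa)
    rows <- lapply(seq_len(6), function(k) suppressWarnings(paired_ttest(sa[k, ], sb[k, ])))
    return(contrast_table(units, rows, q, family = "seed connections"))
  }
  ut <- which(upper.tri(diag(length(labels))), arr.ind = TRUE)
  units <- edge_labels(labels)
  rows <- lapply(seq_len(nrow(ut)), function(k) {
    va <- a[ut[k, 1], ut[k, 2], ]
    vb <- b[ut[k, 1], ut[k, 2], ]
    suppressWarnings(paired_ttest(va, vb))
  })
  contrast_table(units, rows, q, family = sprintf("%d node pairs", nrow(ut)))
}

#' Contrast network metrics between conditions
#'
#' Global efficiency is tested alone (paired t). Nodal metrics (strength,
#' clustering, local efficiency per ROI) form one BH-FDR family.
#'
#' @param a,b Node x node x subject connectivity arrays per condition.
#' @param q FDR level.
#' @return List with `global` (one-row paired test) and `nodal` (contrast
#'   table over metric x node units).
#' @export
network_metric_contrast <- function(a, b, q = 0.05) {
  as_arr <- function(x) if (is.list(x)) simplify2array(x) else x
  a <- as_arr(a); b <- as_arr(b)
  labels <- dimnames(a)[[1]]
  summ <- function(arr) lapply(seq_len(dim(arr)[3]), function(s)
    network_summary(conn_matrix(arr[, , s], labels)))
  sa <- summ(a); sb <- summ(b)
  ge_a <- vapply(sa, `[[`, numeric(1), "global_efficiency")
  ge_b <- vapply(sb, `[[`, numeric(1), "global_efficiency")
  global <- suppressWarnings(paired_ttest(ge_a, ge_b))
  units <- c(sprintf("strength_%s", labels), sprintf("clustering_%s", labels),
             sprintf("local_eff_%s", labels))
  pull <- function(lst, what) t(vapply(lst, `[[`, numeric(length(labels)), what))
  ma <- cbind(pull(sa, "strength"), pull(sa, "clustering"), pull(sa, "local_efficiency"))
  mb <- cbind(pull(sb, "strength"), pull(sb, "clustering"), pull(sb, "local_efficiency"))
  rows <- lapply(seq_along(units), function(k) suppressWarnings(paired_ttest(ma[, k], mb[, k])))
  list(global = global, nodal = contrast_table(units, rows, q, family = "nodal metrics"))
}

#' Required sample size for a paired t-test
#'
#' Smallest integer n such that a two-tailed paired t-test at level `alpha`
#' attains the requested power against a paired effect size dz, using the
#' noncentral t distribution (noncentrality dz sqrt(n), df = n - 1) — the
#' a-priori computation for "difference between two dependent means". With
#' dz = 0.5, alpha = 0.05, power = 0.90 this returns 44.
#'
#' @param dz Paired effect size (> 0).
#' @param alpha Two-tailed significance level.
#' @param power Target power in (0, 1).
#' @param n_max Scan guard (default 1e5).
#' @return Integer sample size (>= 2).
#' @export
required_n_paired <- function(dz = 0.5, alpha = 0.05, power = 0.90, n_max = 1e5) {
  if (dz <= 0) stopf("`dz` must be > 0")
  assert_scalar_num(alpha, "alpha", 1e-12, 1 - 1e-12)
  assert_scalar_num(power, "power", 1e-12, 1 - 1e-12)
  pow <- function(n) {
    tc <- stats::qt(1 - alpha / 2, n - 1)
    ncp <- dz * sqrt(n)
    stats::pt(tc, n - 1, ncp = ncp, lower.tail = FALSE) +
      stats::pt(-tc, n - 1, ncp = ncp)
  }
  n <- 2:1023
  repeat {
    ok <- pow(n) >= power
    if (any(ok)) return(n[which(ok)[1]])
    if (max(n) >= n_max) stopf("requested power not reached by n = %g", n_max)
    n <- (max(n) + 1):min(n_max, max(n) * 2)
  }
}
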