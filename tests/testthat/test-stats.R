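test_that("paired t-test matches hand computation and the one-sample identity", {
  x <- c(2, 4, 6); y <- c(1, 2, 3) # diffs 1, 2, 3
  res <- paired_ttest(x, y)
  expect_equal(res$t, 2 / (1 / sqrt(3)), tolerance = 1e-12)
  expect_equal(res$df, 2L)
  expect_equal(res$dz, 2 / 1, tolerance = 1e-12)
  set.seed(4)
  a <- rnorm(20); b <- rnorm(20)
  one <- t.test(a - b)
  two <- paired_ttest(a, b)
  expect_equal(two$t, unname(one$statistic), tolerance = 1e-12)
  expect_equal(two$p, one$p.value, tolerance = 1e-12)
})

test_that("degenerate and invalid paired inputs follow the documented conventions", {
  x <- rnorm(5)
  expect_warning(res <- paired_ttest(x, x), "zero-variance")
  expect_equal(res$p, 1)
  expect_equal(res$dz, 0)
  expect_true(res$degenerate)
  expect_error(paired_ttest(1, 1), "at least 2")
  expect_error(paired_ttest(1:3, 1:4), "length")
})

test_that("44 paired subjects report 43 degrees of freedom", {
  set.seed(1)
  expect_equal(paired_ttest(rnorm(44), rnorm(44))$df, 43L)
})

test_that("BH adjustment matches the brute-force step-up definition", {
  res <- bh_fdr(c(0.005, 0.01, 0.03, 0.04), q = 0.05)
  expect_true(all(res$significant)) # largest k with p_(k) <= k q / m is k = 4
  expect_equal(bh_fdr(0.04)$p_adj, 0.04)
  expect_true(bh_fdr(0.04)$significant)
  expect_false(any(bh_fdr(rep(1, 6))$significant))
  set.seed(10)
  for (rep in 1:50) {
    p <- runif(sample(1:105, 1))^sample(1:3, 1)
    expect_equal(bh_fdr(p)$p_adj, bh_bruteforce(p), tolerance = 1e-12)
  }
  expect_error(bh_fdr(c(0.1, 1.4)), "\\[0, 1\\]")
})

test_that("BH adjusted p-values are monotone in the raw ranks", {
  set.seed(12)
  p <- runif(40)
  adj <- bh_fdr(p)$p_adj
  expect_true(all(diff(adj[order(p)]) >= -1e-15))
})

test_that("the a-priori paired sample size reproduces the design value", {
  expect_identical(required_n_paired(0.5, 0.05, 0.90), 44L)
  # independent oracle: continuous solution of the same noncentral-t problem
  pt_n <- power.t.test(delta = 1, sd = 1, sig.level = 0.05, power = 0.90,
                       type = "paired")$n
  expect_identical(required_n_paired(1, 0.05, 0.90), as.integer(ceiling(pt_n)))
  expect_identical(required_n_paired(1, 0.05, 1e-4), 2L)
  expect_error(required_n_paired(1e-4, 0.05, 0.99, n_max = 100), "not reached")
})

test_that("required n is monotone in effect size and power", {
  ns_dz <- vapply(c(0.3, 0.5, 0.8, 1.2), function(d) required_n_paired(d), integer(1))
  expect_true(all(diff(ns_dz) <= 0))
  ns_pw <- vapply(c(0.5, 0.8, 0.9, 0.95), function(p) required_n_paired(power = p), integer(1))
  expect_true(all(diff(ns_pw) >= 0))
})

test_that("channel activation contrast detects a planted dz = 0.5 channel at its FDR-corrected power", {
  # independent oracle: BH-corrected detection probability for one true
  # effect of size dz among m - 1 uniform nulls, by direct simulation of the
  # paired t statistic (no epoching, no package contrast code)
  bh_power_oracle <- function(dz, m, n, q = 0.05, reps = 4000) {
    mean(vapply(seq_len(reps), function(r) {
      p <- runif(m)
      d <- rnorm(n, dz, 1)
      p[1] <- 2 * pt(-abs(mean(d) / sd(d) * sqrt(n)), n - 1)
      p.adjust(p, "BH")[1] < q
    }, logical(1)))
  }
  set.seed(100)
  oracle <- bh_power_oracle(0.5, m = 15, n = 44)
  hits <- 0; fp <- 0
  n_rep <- 40
  for (r in 1:n_rep) {
    # per-subject condition stat = mean of 10 trials with trial sd 0.1, so the
    # paired difference has sd sqrt(2) * 0.1 / sqrt(10); scale the Ch06 shift
    # to a planted effect size of dz = 0.5
    delta <- 0.5 * sqrt(2) * 0.1 / sqrt(10)
    sets <- lapply(1:44, function(s) {
      mu_soc <- rnorm(15, 0.3, 0.05)
      mu_ooc <- mu_soc
      mu_ooc[6] <- mu_ooc[6] + delta
      fake_epoch_set(list(OOC = mu_ooc, SOC = mu_soc), trial_sd = 0.1,
                     subject = sprintf("S%02d", s))
    })
    tab <- channel_activation_contrast(sets)
    hits <- hits + tab$significant[tab$unit == "Ch06"]
    fp <- fp + sum(tab$significant[tab$unit != "Ch06"])
  }
  rate <- hits / n_rep
  se <- sqrt(oracle * (1 - oracle) / n_rep)
  expect_lt(abs(rate - oracle), 4 * se)   # matches the oracle power
  expect_gt(rate, 0.3)                     # and detects far above chance
  expect_lte(fp / (n_rep * 14), 0.05)      # null channels controlled by FDR
})

test_that("identical conditions yield no activation rejections", {
  sets <- lapply(1:6, function(s) {
    mu <- rnorm(15, 0.3, 0.05)
    fake_epoch_set(list(OOC = mu, SOC = mu), trial_sd = 0, subject = sprintf("S%02d", s))
  })
  tab <- channel_activation_contrast(sets)
  expect_false(any(tab$significant))
  expect_true(all(tab$p == 1))
})

test_that("activation contrast needs at least two complete subjects", {
  sets <- list(fake_epoch_set(list(OOC = rep(0.3, 15), SOC = rep(0.2, 15))))
  expect_error(channel_activation_contrast(sets), "2 subjects")
})

test_that("connectivity contrast respects families and degenerate inputs", {
  coh <- simulate_plv_cohort(10, seed = 2)
  seed_tab <- connectivity_contrast(coh$a, coh$b, level = "seed")
  expect_equal(nrow(seed_tab), 6)
  expect_named(seed_tab, c("unit", "n", "t", "df", "p", "dz", "degenerate",
                           "p_adj", "significant"), ignore.order = TRUE)
  edge_tab <- connectivity_contrast(coh$a, coh$b, level = "edge")
  expect_equal(nrow(edge_tab), 21) # 7 choose 2 ROI pairs
  ident <- connectivity_contrast(coh$a, coh$a, level = "seed")
  expect_false(any(ident$significant))
  expect_true(all(ident$p == 1))
  bad <- coh$b
  dimnames(bad)[[1]] <- rev(dimnames(bad)[[1]])
  expect_error(connectivity_contrast(coh$a, bad, level = "seed"), "labels")
})

test_that("a planted seed-edge effect is detected and carries the right sign", {
  coh <- simulate_plv_cohort(44, planted = list(rois = c("ROI4", "ROI6"), dz = 0.45),
                             seed = 5)
  tab <- connectivity_contrast(coh$a, coh$b, level = "seed")
  s5 <- tab[tab$unit == "S5", ]
  expect_gt(s5$t, 0)
  expect_gt(s5$dz, 0)
})

test_that("network metric contrast reports global and nodal families", {
  coh <- simulate_plv_cohort(8, seed = 3)
  res <- network_metric_contrast(coh$a, coh$b)
  expect_equal(res$global$df, 7L)
  expect_equal(nrow(res$nodal), 21) # 3 metrics x 7 ROIs
})
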