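sch5 <- generate_paradigm(5, order_seed = 3)

test_that("all-zero spec produces a flat zero series", {
  hemo <- simulate_hemodynamics(sch5, noise = silent_noise(), amplitude = 0,
                                coupling = coupling_spec(strength = 0), seed = 1)
  expect_equal(max(abs(hemo$hbo)), 0)
})

test_that("generator is deterministic in the seed", {
  a <- simulate_hemodynamics(sch5, seed = 11)
  b <- simulate_hemodynamics(sch5, seed = 11)
  c <- simulate_hemodynamics(sch5, seed = 12)
  expect_identical(a$hbo, b$hbo)
  expect_identical(a$hbr, b$hbr)
  expect_gt(max(abs(a$hbo - c$hbo)), 0)
})

test_that("full coupling on a pair yields downstream PLV of 1", {
  sch <- generate_paradigm(8, order_seed = 4) # 476 s blocks > 400 s minimum
  cpl <- coupling_spec(pairs = list(c("Ch01", "Ch02")), freq_hz = 0.02,
                       strength = 1, lags_rad = c(Ch01 = 0, Ch02 = 0.4))
  hemo <- simulate_hemodynamics(sch, coupling = cpl, noise = silent_noise(band_sd_um = 0.15),
                                amplitude = 0, seed = 5)
  filt <- bandpass_series(resample_series(hemo))
  M <- plv_matrix(condition_segment(filt, sch, "OOC"))
  expect_gt(M["Ch01", "Ch02"], 1 - 1e-3)
})

test_that("coupling frequency and channel references are validated", {
  expect_error(simulate_hemodynamics(sch5, coupling = coupling_spec(freq_hz = 5)),
               "Nyquist")
  expect_error(
    simulate_hemodynamics(sch5, coupling = coupling_spec(pairs = list(c("Ch01", "Ch99")),
                                                         strength = 0.5)),
    "unknown channels")
})

test_that("ΔHbR is the inverted scaled companion of ΔHbO", {
  hemo <- simulate_hemodynamics(sch5, seed = 2)
  expect_lt(cor(hemo$hbo[, 1], hemo$hbr[, 1]), -0.9)
  fit <- coef(lm(as.vector(hemo$hbr) ~ as.vector(hemo$hbo)))
  expect_equal(unname(fit[2]), -1 / 3, tolerance = 0.05)
})

test_that("planted-pair PLV increases monotonically with coupling strength", {
  sch <- generate_paradigm(8, order_seed = 4)
  grid <- c(0, 0.25, 0.5, 0.75, 1)
  mean_plv <- vapply(seq_along(grid), function(k) {
    cpl <- coupling_spec(pairs = list(c("Ch03", "Ch04")), freq_hz = 0.02,
                         strength = grid[k])
    hemo <- simulate_hemodynamics(sch, coupling = cpl, amplitude = 0,
                                  noise = silent_noise(band_sd_um = 0.15,
                                                       white_sd_um = 0.05),
                                  seed = 100)
    filt <- bandpass_series(resample_series(hemo))
    M <- plv_matrix(condition_segment(filt, sch, "OOC"))
    M["Ch03", "Ch04"]
  }, numeric(1))
  expect_identical(order(mean_plv), seq_along(grid)) # Spearman rho = 1
})

test_that("designated coupled pairs outrank non-designated pairs end-to-end", {
  sch <- generate_paradigm(8, order_seed = 4)
  pairs <- list(c("Ch01", "Ch02"), c("Ch05", "Ch09"), c("Ch10", "Ch13"))
  cpl <- coupling_spec(pairs = pairs, freq_hz = 0.02, strength = 0.9)
  hits <- vapply(1:10, function(rep) {
    hemo <- simulate_hemodynamics(sch, coupling = cpl, amplitude = 0, seed = 200 + rep)
    filt <- bandpass_series(resample_series(hemo))
    M <- plv_matrix(condition_segment(filt, sch, "OOC"))
    des <- vapply(pairs, function(p) M[p[1], p[2]], numeric(1))
    ut <- M[upper.tri(M)]
    mean(des) > (sum(ut) - sum(des)) / (length(ut) - length(des))
  }, logical(1))
  expect_true(all(hits))
})

test_that("behavior simulator respects the schedule and the spec", {
  eff <- behavior_effect_spec(low_price_prob = c(OOC = 0, SOC = 1))
  log <- simulate_behavior(sch5, eff, seed = 3)
  expect_equal(nrow(log), 2 * 5 * 3)
  expect_true(all(log$rt_ms > 0 & log$rt_ms <= 8000))
  expect_equal(sum(log$price_tier == "low" & log$condition == "SOC"), 15)
  expect_equal(sum(log$price_tier == "low" & log$condition == "OOC"), 0)
  expect_identical(log, simulate_behavior(sch5, eff, seed = 3))
  log10 <- simulate_behavior(generate_paradigm(10, order_seed = 1), seed = 1)
  expect_equal(as.vector(table(log10$condition)), c(30, 30))
})

test_that("group RT test holds its size under identical RT distributions", {
  sch <- generate_paradigm(10, order_seed = 1)
  eff <- behavior_effect_spec(rt_diff_subject_sd = 1e-9)
  nonsig <- vapply(1:100, function(r) {
    log <- simulate_behavior_cohort(12, schedule = sch, effects = eff, seed = 4000 + r)
    rt_contrast(log)$group$p > 0.05
  }, logical(1))
  expect_gte(sum(nonsig), 90)
})
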