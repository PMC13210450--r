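band_marked <- function(x, fs = 2) {
  hemo_series(as.matrix(x), fs = fs, channels = sprintf("Ch%02d", seq_len(ncol(as.matrix(x)))),
              band = c(0.005, 0.05))
}

test_that("instantaneous phase advances at the signal frequency", {
  t <- seq(0, 3000, by = 0.5)
  h <- band_marked(sin(2 * pi * 0.02 * t))
  ph <- instantaneous_phase(h, edge_trim = 50)
  slope <- mean(diff(signal::unwrap(ph$phase[, 1]))) * 2 # rad/s at 2 Hz
  expect_equal(slope, 2 * pi * 0.02, tolerance = 0.01)
})

test_that("cos leads sin by pi/2", {
  t <- seq(0, 3000, by = 0.5)
  h <- band_marked(cbind(cos(2 * pi * 0.02 * t), sin(2 * pi * 0.02 * t)))
  ph <- instantaneous_phase(h, edge_trim = 100)
  mid <- seq(round(nrow(ph$phase) * 0.4), round(nrow(ph$phase) * 0.6))
  d <- Arg(exp(1i * (ph$phase[mid, 1] - ph$phase[mid, 2])))
  expect_equal(mean(d), pi / 2, tolerance = 0.01)
})

test_that("phase extraction validates trim length and band annotation", {
  short <- band_marked(rnorm(100))
  expect_error(instantaneous_phase(short, edge_trim = 50), "too short")
  unmarked <- hemo_series(matrix(rnorm(1000), ncol = 1), fs = 2, channels = "Ch01")
  expect_warning(instantaneous_phase(unmarked, edge_trim = 10), "band")
})

test_that("PLV matches its closed-form cases", {
  phi <- runif(500, -pi, pi)
  expect_equal(plv(phi, phi), 1)
  expect_lt(plv(rep(c(0, pi), 50), rep(0, 100)), 1e-12)       # antipodal cancellation
  expect_lt(plv(c(0, pi / 2, pi, 3 * pi / 2), rep(0, 4)), 1e-12) # four-point symmetry
  expect_error(plv(phi, phi[-1]), "length")
  expect_error(plv(1, 2), "2 samples")
})

test_that("PLV is invariant to a constant phase offset and symmetric", {
  set.seed(1)
  for (rep in 1:20) {
    a <- runif(200, -pi, pi); b <- runif(200, -pi, pi); c0 <- runif(1, -pi, pi)
    expect_equal(plv(a + c0, b), plv(a, b), tolerance = 1e-12)
    expect_equal(plv(a, b), plv(b, a), tolerance = 1e-15)
  }
})

test_that("uniform-phase PLV follows the sqrt(pi)/(2 sqrt(N)) null mean", {
  set.seed(7)
  reps <- vapply(1:300, function(r) plv(runif(1000, -pi, pi), rep(0, 1000)), numeric(1))
  se <- sd(reps) / sqrt(length(reps))
  expect_lt(abs(mean(reps) - sqrt(pi) / (2 * sqrt(1000))), 4 * se)
})

test_that("the channel PLV matrix is symmetric with unit diagonal in [0,1]", {
  set.seed(3)
  x <- matrix(rnorm(1300 * 4), ncol = 4)
  h <- bandpass_series(hemo_series(x, fs = 2, channels = sprintf("Ch%02d", 1:4)))
  M <- plv_matrix(h)
  expect_equal(max(abs(M - t(M))), 0)
  expect_equal(unname(diag(M)), rep(1, 4))
  expect_true(all(M >= 0 & M <= 1))
})

test_that("independent band-filtered noise stays weakly synchronized", {
  set.seed(8)
  x <- matrix(rnorm(1201 * 15), ncol = 15) # 600 s at 2 Hz
  h <- bandpass_series(hemo_series(x, fs = 2, channels = sprintf("Ch%02d", 1:15)))
  M <- plv_matrix(h)
  expect_lt(median(M[upper.tri(M)]), 0.5)
})

test_that("segments below the minimum duration are rejected", {
  x <- matrix(rnorm(700), ncol = 1) # 350 s at 2 Hz
  h <- band_marked(x)
  expect_error(plv_matrix(h), "shorter than")
})

test_that("ROI aggregation averages cross-ROI channel pairs", {
  ch <- sprintf("Ch%02d", 1:15)
  M1 <- conn_matrix(matrix(1, 15, 15), ch)
  R1 <- roi_mean_connectivity(M1)
  expect_true(all(R1 == 1))
  m <- matrix(0.3, 15, 15); diag(m) <- 1
  m[1, 8] <- m[8, 1] <- 0.4 # Ch01-Ch08
  m[2, 8] <- m[8, 2] <- 0.6 # Ch02-Ch08
  R <- roi_mean_connectivity(conn_matrix(m, ch))
  expect_equal(unname(R["ROI1", "ROI4"]), 0.5)
  # bounds: every ROI entry lies within its constituent channel entries
  set.seed(5)
  mr <- matrix(runif(225, 0.1, 0.9), 15); mr <- (mr + t(mr)) / 2; diag(mr) <- 1
  Mr <- conn_matrix(mr, ch)
  Rr <- roi_mean_connectivity(Mr)
  map <- roi_map()
  for (a in names(map$channels)) for (b in names(map$channels)) {
    if (a == b) next
    block <- Mr[map$channels[[a]], map$channels[[b]], drop = FALSE]
    expect_gte(Rr[a, b], min(block) - 1e-12)
    expect_lte(Rr[a, b], max(block) + 1e-12)
  }
})

test_that("the seed profile is the ROI4 row in target order", {
  rois <- names(roi_map()$channels)
  R <- diag(7) * 0 + 1
  vals <- c(0.1, 0.2, 0.3, 0.5, 0.6, 0.7)
  R[4, c(1:3, 5:7)] <- vals; R[c(1:3, 5:7), 4] <- vals
  diag(R) <- 1
  S <- seed_profile(conn_matrix(R, rois))
  expect_equal(unname(S), vals)
  expect_named(S, sprintf("S%d", 1:6))
  expect_equal(unname(seed_profile(conn_matrix(matrix(1, 7, 7), rois))), rep(1, 6))
  # permutation naturality: reordering the matrix rows/columns permutes S along
  perm <- c(2, 1, 3, 4, 6, 5, 7)
  Sp <- seed_profile(conn_matrix(R[perm, perm], rois[perm]))
  expect_equal(sort(unname(Sp)), sort(vals))
  expect_equal(Sp[["S5"]], R[perm, perm][rois[perm] == "ROI4", rois[perm] == "ROI6"])
})

test_that("binarization uses a strict threshold and excludes the diagonal", {
  m <- matrix(c(1, 0.69, 0.70, 0.69, 1, 0.71, 0.70, 0.71, 1), 3)
  M <- conn_matrix(m, c("a", "b", "c"))
  A <- binarize(M, 0.7)
  expect_false(A["a", "b"]); expect_false(A["a", "c"]); expect_true(A["b", "c"])
  expect_false(any(diag(A)))
  expect_true(all(binarize(M, 0)[upper.tri(m)]))
  expect_false(any(binarize(M, 1)))
})
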