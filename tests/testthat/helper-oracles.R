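# Independent oracles and small fixture builders used across tests.

# Noise spec with every stochastic/physiological component silenced (overridable).
silent_noise <- function(...) {
  args <- utils::modifyList(
    list(cardiac_um = 0, respiratory_um = 0, mayer_um = 0,
         white_sd_um = 0, drift_um_per_s = 0, band_sd_um = 0),
    list(...))
  do.call(noise_spec, args)
}

# Least-squares amplitude of a sinusoid of frequency f in y sampled at times t.
ls_amplitude <- function(y, t, f) {
  X <- cbind(sin(2 * pi * f * t), cos(2 * pi * f * t))
  cf <- qr.solve(X, y)
  sqrt(sum(cf^2))
}

# Floyd-Warshall all-pairs shortest paths on a length matrix (Inf = no edge).
floyd_warshall <- function(L) {
  n <- nrow(L)
  D <- L
  diag(D) <- 0
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      via <- D[i, k] + D[k, ]
      D[i, ] <- pmin(D[i, ], via)
    }
  }
  D
}

# Brute-force weighted global efficiency from the reciprocal-weight lengths.
global_efficiency_bruteforce <- function(W) {
  n <- nrow(W)
  L <- ifelse(W > 0, 1 / W, Inf)
  D <- floyd_warshall(L)
  inv <- 1 / D
  diag(inv) <- 0
  sum(inv[is.finite(inv)]) / (n * (n - 1))
}

# Brute-force Benjamini-Hochberg step-up adjusted p-values.
bh_bruteforce <- function(p) {
  m <- length(p)
  o <- order(p)
  adj_sorted <- numeric(m)
  for (k in seq_len(m)) {
    adj_sorted[k] <- min(1, min(m * p[o][k:m] / (k:m)))
  }
  out <- numeric(m)
  out[o] <- adj_sorted
  out
}

# Random symmetric weighted graph on n nodes with edge density `dens`.
random_weighted_graph <- function(n, dens = 0.6) {
  W <- matrix(0, n, n)
  ut <- upper.tri(W)
  w <- ifelse(runif(sum(ut)) < dens, runif(sum(ut), 0.05, 1), 0)
  W[ut] <- w
  W + t(W)
}

# Fabricated epoch_set whose per-trial task-window mean equals `stat` plus
# trial noise, for testing the activation contrast without the signal chain.
fake_epoch_set <- function(stat_by_cond, n_trials = 10, trial_sd = 0.05,
                           channels = sprintf("Ch%02d", 1:15),
                           subject = "S01") {
  times <- seq(-1, 60.5, by = 4)
  conds <- names(stat_by_cond)
  n_ep <- n_trials * length(conds)
  data <- array(0, c(length(times), length(channels), n_ep),
                dimnames = list(NULL, channels, NULL))
  idx <- data.frame(condition = rep(conds, each = n_trials),
                    trial = rep(seq_len(n_trials), length(conds)),
                    onset = 0, subject = subject, stringsAsFactors = FALSE)
  for (k in seq_len(n_ep)) {
    mu <- stat_by_cond[[idx$condition[k]]] # length-n_channels vector
    data[times >= 0, , k] <- matrix(mu + rnorm(length(channels), sd = trial_sd),
                                    sum(times >= 0), length(channels), byrow = TRUE)
  }
  structure(list(data = data, index = idx, times = times, fs = 0.25,
                 channels = channels, baseline_window = c(-1, 0),
                 dropped = data.frame()),
            class = "epoch_set")
}
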