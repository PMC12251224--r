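## Spike-band filtering, threshold detection, PSTHs and rate tests.

.wb_session <- function(wb, fs_wb = 20000, onsets = numeric(0)) {
  n_lfp <- max(3, round(ncol(wb) / fs_wb * 1000))
  recording_session(matrix(0, nrow(wb), max(n_lfp, 10)), 1000, onsets,
                    "FLASH", wideband_signals = wb, fs_wideband = fs_wb)
}

test_that("spike-band filter passes 1 kHz, rejects 50 Hz, keeps latency", {
  fs <- 20000; t <- seq(0, 2 - 1 / fs, by = 1 / fs)
  x1k <- sin(2 * pi * 1000 * t); x50 <- sin(2 * pi * 50 * t)
  tpl <- sin(2 * pi * seq(0, 1, length.out = 21))
  sp <- rep(0, length(t)); sp[10000 + seq_along(tpl)] <- tpl
  s <- .wb_session(rbind(x1k, x50, sp), fs)
  f <- filter_mua(s)
  mid <- seq(round(fs / 2), round(1.5 * fs))
  expect_lt(abs(max(f[1, mid]) - 1), 0.05)
  expect_lt(20 * log10(max(abs(f[2, mid])) / 1), -40)
  expect_lte(abs(which.max(f[3, ]) - which.max(sp)), 1)
  expect_error(filter_mua(recording_session(matrix(0, 3, 5000), 1000,
                                            numeric(0), "FLASH")),
               "wideband")
})

test_that("the robust threshold equals the factor in noise-SD units", {
  set.seed(71)
  x <- matrix(rnorm(2e6), 1)
  sp <- detect_spikes(x, fs = 20000, alpha = 3.5)
  expect_equal(sp$threshold[1], 3.5, tolerance = 0.01)
  ## estimator consistency: robust SD within 1% of truth at large n
  expect_lt(abs(robust_noise_sd(x[1, ] * 2.7) - 2.7) / 2.7, 0.01)
  expect_error(detect_spikes(x, 20000, alpha = 0), "positive")
})

test_that("well-separated injected events are each detected once", {
  fs <- 20000
  set.seed(72)
  x <- rnorm(fs * 5, sd = 1)
  tpl <- 10 * sin(2 * pi * seq(0, 1, length.out = round(fs / 1000) + 1))
  at <- c(1.0, 2.5, 4.0)
  for (a in at) x[round(a * fs) + seq_along(tpl)] <- x[round(a * fs) +
                                                         seq_along(tpl)] + tpl
  f <- filter_mua(.wb_session(rbind(x, x, x), fs))
  sp <- detect_spikes(f, fs, alpha = 3.5)
  ## count only detections near the injections; noise crossings live
  ## elsewhere and are assessed in the false-rate check below
  near <- function(det) vapply(at, function(a)
    any(abs(det - a) < 0.5e-3), logical(1))
  expect_true(all(near(sp$spike_times_s[[1]])))
  ## each injection produces exactly one detection within its half ms
  per_event <- vapply(at, function(a)
    sum(abs(sp$spike_times_s[[1]] - a) < 0.5e-3), integer(1))
  expect_equal(per_event, c(1L, 1L, 1L))
})

test_that("degenerate input yields zero threshold and no events", {
  sp <- detect_spikes(matrix(0, 2, 30000), fs = 20000)
  expect_equal(sp$threshold, c(0, 0))
  expect_equal(lengths(sp$spike_times_s), c(0L, 0L))
})

test_that("false detections on pure noise match the crossing-rate estimate", {
  fs <- 20000
  set.seed(73)
  f <- filter_mua(.wb_session(matrix(rnorm(3 * fs * 10), 3), fs))
  sp <- detect_spikes(f, fs, alpha = 3.5)
  x <- f[1, ]
  ## discrete Gaussian upcrossing oracle: P(x_k < u < x_{k+1}) for a
  ## Gaussian pair with the observed lag-1 correlation, by Monte Carlo
  rho <- cor(x[-1], x[-length(x)])
  set.seed(990)
  z1 <- rnorm(2e6); z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(2e6)
  rate_pred <- fs * mean(z1 < 3.5 & z2 > 3.5)
  rate_obs <- length(sp$spike_times_s[[1]]) / 10
  expect_lt(rate_obs / rate_pred, 2)
  expect_gt(rate_obs / rate_pred, 0.5)
})

test_that("PSTH counts convert to rates and average as specified", {
  fs <- 20000
  onsets <- seq(1, 100.5, by = 1)
  sp <- structure(list(spike_times_s = list(onsets + 0.005),
                       threshold = 1, alpha = 3.5, fs = fs),
                  class = "spike_train_set")
  lay <- data.frame(contact = 1, label = "L56")
  ps <- compute_psth(sp, onsets, lay)
  expect_equal(as.numeric(ps$rates["L56", 1]), 100)
  expect_true(all(ps$rates["L56", -1] == 0))
  ## no spikes at all
  sp0 <- structure(list(spike_times_s = list(numeric(0)), threshold = 1,
                        alpha = 3.5, fs = fs), class = "spike_train_set")
  expect_true(all(compute_psth(sp0, onsets, lay)$rates == 0))
  expect_error(compute_psth(sp, onsets, lay, bin_ms = 7), "divide")
  ## homogeneous Poisson rate is recovered
  set.seed(74)
  st <- sort(runif(20 * 300, 0, 300))
  spp <- structure(list(spike_times_s = list(st), threshold = 1,
                        alpha = 3.5, fs = fs), class = "spike_train_set")
  pp <- compute_psth(spp, seq(2, 201, by = 1), lay)
  expect_equal(mean(pp$trial_rates$rate), 20, tolerance = 1)
})

test_that("peak/trough selection windows behave and cover a quarter each", {
  lab <- data.frame(trial = 1:3, phase_deg = c(0, 90, 179), valid = TRUE)
  expect_equal(select_phase_locked_trials(lab, "peak"), 1L)
  expect_equal(select_phase_locked_trials(lab, "trough"), 3L)
  expect_error(select_phase_locked_trials(lab, "peak", 100), "90")
  set.seed(75)
  labu <- data.frame(trial = 1:2000, phase_deg = runif(2000, -180, 180),
                     valid = TRUE)
  for (tg in c("peak", "trough")) {
    frac <- length(select_phase_locked_trials(labu, tg)) / 2000
    expect_lt(abs(frac - 0.25), 0.05)
  }
})

test_that("firing-rate comparisons match closed-form t statistics", {
  r0 <- compare_firing(c(1, 2, 3), c(1, 2, 3), "paired")
  expect_equal(r0$t, 0)
  expect_equal(r0$p_value, 1)
  set.seed(76)
  a <- rnorm(100, 5); b <- rnorm(100, 10)
  r <- compare_firing(a, b, "unpaired")
  t_hand <- (mean(a) - mean(b)) /
    sqrt(((99 * var(a) + 99 * var(b)) / 198) * (2 / 100))
  expect_equal(r$t, t_hand, tolerance = 1e-10)
  expect_lt(r$p_value, 1e-6)
  expect_error(compare_firing(1, 2), "2 trials")
  expect_error(compare_firing(1:3, 1:4, "paired"), "equal")
})

test_that("deep-rate excess is significant while a null phase effect is not", {
  gs <- memo("mua_pair", generate_session(
    synth_config(duration_s = 75, include_wideband = TRUE, seed = 77)))
  lay <- data.frame(contact = 1:23, label = gs$truth$layer_labels)
  sp <- detect_spikes(filter_mua(gs$flash_ac), gs$flash_ac$fs_wideband)
  ps <- compute_psth(sp, gs$flash_ac$stim_onsets_s, lay)
  rate <- function(l) ps$trial_rates$rate[ps$trial_rates$layer == l]
  r <- compare_firing(rate("L56"), rate("L23"), "unpaired")
  expect_gt(r$t, 0)
  expect_lt(r$p_value, 0.01)
  ## no spike-phase coupling was injected: peak vs trough is null
  lab <- data.frame(trial = seq_along(gs$truth$phases_deg),
                    phase_deg = gs$truth$phases_deg, valid = TRUE)
  pk <- select_phase_locked_trials(lab, "peak")
  tr <- select_phase_locked_trials(lab, "trough")
  r2 <- compare_firing(rate("L56")[pk], rate("L56")[tr], "unpaired")
  expect_gt(r2$p_value, 0.05)
})
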