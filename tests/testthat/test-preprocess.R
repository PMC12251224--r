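## Frequency-response and epoch-level contracts of the LFP path.

.sine_session <- function(freqs, amps, fs = 2000, dur = 30) {
  t <- seq(0, dur - 1 / fs, by = 1 / fs)
  x <- rowSums(mapply(function(f, a) a * sin(2 * pi * f * t), freqs, amps))
  toy_session(rbind(x, x, x), fs = fs)
}

test_that("LFP filter passes the band, kills DC, line noise and rate", {
  fs <- 2000; dur <- 30
  t <- seq(0, dur - 1 / fs, by = 1 / fs)
  mid <- seq(round(length(t) / 3), round(2 * length(t) / 3)) / 2  # at 1 kHz
  s60 <- filter_lfp(.sine_session(60, 1))
  expect_equal(s60$fs_lfp, 1000)
  rms <- function(x) sqrt(mean(x^2))
  expect_lt(rms(s60$lfp_signals[1, mid]), 0.05 * rms(sin(2 * pi * 60 * t)))
  sdc <- filter_lfp(toy_session(matrix(5, 3, fs * dur), fs = fs))
  expect_lt(abs(mean(sdc$lfp_signals[1, mid])), 0.01)
  s10 <- filter_lfp(.sine_session(10, 1))
  expect_lt(abs(max(s10$lfp_signals[1, mid]) - 1), 0.05)
  expect_error(filter_lfp(toy_session(matrix(0, 3, 2500 * 3), fs = 2500)),
               "integer multiple")
})

test_that("zero-phase filtering shifts a delayed copy by exactly the delay", {
  fs <- 2000
  n <- fs * 20
  wave <- evoked_kernel(seq(0, 250, by = 1000 / fs), 0.8, 1.2)
  x <- rep(0, n)
  onsets <- c(5, 9.5)
  for (o in onsets) x[o * fs + seq_along(wave)] <- wave
  delay_s <- 0.064
  x2 <- c(rep(0, delay_s * fs), x)[seq_len(n)]
  s1 <- filter_lfp(toy_session(rbind(x, x, x), fs = fs, onsets = onsets))
  s2 <- filter_lfp(toy_session(rbind(x2, x2, x2), fs = fs,
                               onsets = onsets + delay_s))
  e1 <- extract_components(epoch_and_baseline(s1))
  e2 <- extract_components(epoch_and_baseline(s2))
  expect_equal(e1$p1_lat_ms, e2$p1_lat_ms)
  expect_equal(e1$n1_lat_ms, e2$n1_lat_ms)
})

test_that("epochs span -50..250 ms with a zero baseline", {
  fs <- 1000
  set.seed(4)
  x <- matrix(rnorm(3 * fs * 60), 3)
  s <- toy_session(x, fs = fs, onsets = seq(1, 59, by = 0.5))
  ep <- epoch_and_baseline(s)
  expect_equal(ep$t_ms, -50:250)
  expect_equal(dim(ep$data), c(117, 3, 301))
  bl <- ep$t_ms >= -50 & ep$t_ms < 0
  expect_lt(max(abs(apply(ep$data[, , bl], c(1, 2), mean))), 1e-10)
  ## constant signal epochs are all zero after baseline correction
  sc <- toy_session(matrix(3, 3, fs * 10), fs = fs, onsets = c(2, 4))
  expect_true(all(epoch_and_baseline(sc)$data == 0))
  ## onsets at the very edge are dropped with a warning, not an error
  se <- toy_session(x, fs = fs, onsets = c(0.02, 5, 59.99))
  expect_warning(epe <- epoch_and_baseline(se), "dropped")
  expect_equal(dim(epe$data)[1], 1)
})

test_that("the +/-5 SD envelope rejects exactly the deviant trial", {
  fs <- 1000
  set.seed(5)
  n_tr <- 100
  ep <- make_epochs(n_tr, 4, 301, seed = 5)
  ep$data[37, , ] <- ep$data[37, , ] * 20
  out <- reject_trials(ep)
  ## independent envelope oracle, computed directly
  mu <- apply(ep$data, c(2, 3), mean)
  sdv <- apply(ep$data, c(2, 3), sd)
  bad_oracle <- sapply(seq_len(n_tr), function(i)
    any(ep$data[i, , ] < mu - 5 * sdv | ep$data[i, , ] > mu + 5 * sdv))
  expect_equal(!out$keep_mask, bad_oracle)
  expect_false(out$keep_mask[37])
  expect_equal(sum(!out$keep_mask), 1)
  ## idempotence (the mask, not the data, is updated)
  expect_equal(reject_trials(out)$keep_mask, out$keep_mask)
})

test_that("degenerate epochs reject nothing", {
  ep <- make_epochs(5, 3, 100, seed = 6)
  for (i in 2:5) ep$data[i, , ] <- ep$data[1, , ]
  expect_true(all(reject_trials(ep)$keep_mask))
  ep0 <- make_epochs(4, 3, 100, seed = 7); ep0$data[] <- 0
  expect_true(all(reject_trials(ep0)$keep_mask))
  ep1 <- make_epochs(1, 3, 100, seed = 8)
  expect_error(reject_trials(ep1), "2 trials")
})

test_that("component extraction recovers injected amplitudes and latencies", {
  t_ms <- -50:250
  wave <- evoked_kernel(t_ms, 0.8, 1.2)
  ep <- make_epochs(2, 3, 301, seed = 9)
  ep$data[] <- 0
  for (i in 1:2) for (j in 1:3) ep$data[i, j, ] <- wave
  ep$t_ms <- t_ms
  comp <- extract_components(ep)
  ## the two Gaussian lobes overlap slightly, so recovery is <1% not exact
  expect_equal(comp$p1_amp, rep(0.8, 6), tolerance = 2e-3)
  expect_equal(comp$p1_lat_ms, rep(75, 6))
  expect_equal(comp$n1_amp, rep(-1.2, 6), tolerance = 2e-3)
  expect_equal(comp$n1_lat_ms, rep(120, 6))
  ## flat trial: zero amplitudes, earliest-sample tie-break for latency
  ep$data[] <- 0
  comp0 <- extract_components(ep)
  expect_true(all(comp0$p1_amp == 0 & comp0$n1_amp == 0))
  expect_true(all(comp0$p1_lat_ms == 55 & comp0$n1_lat_ms == 100))
})
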