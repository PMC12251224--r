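## Units, field gradients and phase-label conventions.

test_that("narrowband extraction removes the gain and keeps the band", {
  fs <- 2000; dur <- 60
  t <- seq(0, dur - 1 / fs, by = 1 / fs)
  x <- 10 * cos(2 * pi * 1.5 * t) + 2 * sin(2 * pi * 60 * t)
  s <- toy_session(rbind(x, x, x), fs = fs, condition = "FLASH_AC")
  nb <- extract_ac_waveform(s)
  mid <- seq(round(length(t) / 8), round(3 * length(t) / 8))  # 1 kHz index
  expect_equal(max(nb[1, mid]), 1.0, tolerance = 0.02)
  ## 60 Hz content down by > 40 dB
  p60 <- lamtacs:::power_at(nb[1, mid], 1000, 60)
  expect_lt(10 * log10(p60 / (2^2 / 2 / 100)), -40)
  expect_error(extract_ac_waveform(toy_session(rbind(x, x, x), fs = fs)),
               "FLASH_AC")
})

test_that("narrowband output of white noise is band-limited below 2 Hz", {
  fs <- 2000
  set.seed(31)
  x <- matrix(rnorm(3 * fs * 60), 3)
  nb <- extract_ac_waveform(toy_session(x, fs = fs, condition = "FLASH_AC"))
  z <- nb[1, seq(2000, ncol(nb) - 2000)]
  P <- Mod(stats::fft(z - mean(z)))^2
  fr <- (seq_along(P) - 1) * 1000 / length(P)
  hi <- sum(P[fr > 3 & fr < 500]); tot <- sum(P[fr > 0 & fr < 500])
  expect_lt(hi / tot, 0.01)
})

test_that("field computation matches finite-difference oracles", {
  expect_equal(compute_efield(c(0, 1, 2, 3), 0.1), rep(10, 4))
  expect_equal(compute_efield(rep(2.5, 6), 0.1), rep(0, 6))
  v <- (0:4)^2   # quadratic: dv/di = 2i, spacing 0.1 mm
  ef <- compute_efield(v, 0.1)
  expect_equal(ef[2:4], 2 * (1:3) / 0.1)
  expect_error(compute_efield(c(1, 2), 0.1), "3 contacts")
  expect_error(compute_efield(1:5, 0), "positive")
})

test_that("amplitude/phase extraction follows the cosine convention", {
  fs <- 1000; t <- seq(0, 20 - 1 / fs, by = 1 / fs)
  r <- extract_amp_phase(2 * cos(2 * pi * 1.5 * t), fs)
  expect_equal(r$amplitude, 2, tolerance = 1e-3)
  expect_lt(lamtacs:::circ_diff_deg(r$phase_deg, 0), 1)
  expect_equal(r$f_peak, 1.5, tolerance = 0.05)
  r2 <- extract_amp_phase(2 * cos(2 * pi * 1.5 * t - pi / 2), fs)
  expect_lt(lamtacs:::circ_diff_deg(r2$phase_deg, -90), 1)
  r3 <- extract_amp_phase(3 * cos(2 * pi * 1.5 * t) +
                            1 * cos(2 * pi * 5 * t), fs)
  expect_equal(r3$f_peak, 1.5, tolerance = 0.05)
  expect_equal(r3$amplitude, 3, tolerance = 0.02)
  expect_error(extract_amp_phase(rep(0, 1000), fs), "all-zero")
})

test_that("Hilbert phase labels follow the analytic-signal convention", {
  fs <- 1000; dur <- 30
  t <- seq(0, dur - 1 / fs, by = 1 / fs)
  ac <- cos(2 * pi * 1.5 * t)
  Tp <- 1 / 1.5
  ## onsets at a peak and a quarter-period after a peak (mid-record)
  on <- c(15 * Tp, 15 * Tp + Tp / 4)
  lab <- phase_at_onsets(ac, on)
  expect_equal(lab$phase_deg[1], 0, tolerance = 1)
  expect_equal(lab$phase_deg[2], 90, tolerance = 1)
  ## edge-guarded onsets are marked invalid
  lab2 <- phase_at_onsets(ac, c(0.1, 15, dur - 0.1))
  expect_equal(lab2$valid, c(FALSE, TRUE, FALSE))
})

test_that("incommensurate onset sampling of the carrier is uniform", {
  fs <- 1000; dur <- 120
  t <- seq(0, dur - 1 / fs, by = 1 / fs)
  ac <- cos(2 * pi * 1.5 * t)
  on <- seq(2, dur - 2, by = 1 / 2.3)[1:200]
  lab <- phase_at_onsets(ac, on)
  expect_gt(rayleigh_test(lab)$p_value, 0.05)
})

test_that("Hilbert and Fourier phases agree on a stationary sinusoid", {
  fs <- 1000; dur <- 40
  t <- seq(0, dur - 1 / fs, by = 1 / fs)
  for (ph0 in c(-120, 30, 160)) {
    ac <- 2 * cos(2 * pi * 1.5 * t + lamtacs:::deg2rad(ph0))
    hl <- phase_at_onsets(ac, 20)$phase_deg
    ## Fourier phase at the record start, advanced to the onset time
    fft_ph <- extract_amp_phase(ac, fs)$phase_deg + 360 * 1.5 * 20
    expect_lt(lamtacs:::circ_diff_deg(hl, fft_ph), 5)
  }
})

test_that("virtual labels equal the closed-form phase sequence", {
  fs <- 2000
  s <- toy_session(matrix(0, 3, fs * 30), fs = fs,
                   onsets = (0:20) / 1.5, condition = "FLASH")
  expect_equal(virtual_ac_labels(s, 1.5)$phase_deg, rep(0, 21))
  k <- 0:50
  s2 <- toy_session(matrix(0, 3, fs * 60), fs = fs,
                    onsets = 1 + k / 2.3, condition = "FLASH")
  oracle <- wrap_deg(360 * 1.5 * (1 + k / 2.3))
  expect_equal(virtual_ac_labels(s2, 1.5)$phase_deg, oracle)
  s3 <- toy_session(matrix(0, 3, fs * 30), fs = fs, onsets = 2,
                    condition = "FLASH_AC")
  expect_error(virtual_ac_labels(s3), "FLASH")
})

test_that("the session field profile recovers the generator's field", {
  gs <- small_pair()
  nb <- extract_ac_waveform(filter_lfp(gs$flash_ac))
  fp <- field_profile(nb, gs$flash_ac)
  expect_equal(attr(fp, "dominant_frequency_hz"), 1.5, tolerance = 0.05)
  tr <- gs$truth
  interior <- 2:22
  expect_lt(max(abs(fp$efield_V_per_m[interior] -
                      compute_efield(tr$potential_mV, 0.1)[interior]) /
                  max(tr$efield_V_per_m)), 0.02)
  ## the estimated-field maximum sits in layers 2/3, as injected
  expect_true(tr$layer_labels[which.max(fp$efield_V_per_m)] == "L23")
})
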