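## Blind source separation and sinusoid-subtraction contracts.

## sign/permutation alignment: best column matching by |correlation| or
## |dot product|; returns the aligned distance for oracle comparisons.
.align_cols <- function(A, B) {
  p <- ncol(A)
  perm <- integer(p); sgn <- numeric(p)
  used <- logical(p)
  for (j in seq_len(p)) {
    d <- abs(crossprod(A, B[, j]))
    d[used] <- -Inf
    i <- which.max(d)
    perm[j] <- i; used[i] <- TRUE
    sgn[j] <- sign(sum(A[, i] * B[, j]))
  }
  A[, perm] %*% diag(sgn, p)
}

test_that("joint diagonalizer leaves diagonal stacks alone", {
  Ms <- list(diag(c(3, 1, 0.5)), diag(c(2, 5, 1)))
  V <- joint_diagonalize(Ms)
  expect_equal(abs(V), diag(3), tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("joint diagonalizer recovers a planted rotation", {
  set.seed(11)
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  Ms <- list(R %*% diag(c(4, 1)) %*% t(R), R %*% diag(c(1, 6)) %*% t(R))
  V <- joint_diagonalize(Ms)
  expect_lt(norm(.align_cols(V, R) - R, "F"), 1e-8)
  ## residual off-diagonal mass is negligible
  expect_lt(attr(V, "off_diag_mass"), 1e-16)
})

test_that("on a single matrix the diagonalizer equals an eigendecomposition", {
  set.seed(12)
  A <- crossprod(matrix(rnorm(25), 5))
  V <- joint_diagonalize(list(A))
  E <- eigen(A, symmetric = TRUE)$vectors
  expect_lt(norm(.align_cols(V, E) - E, "F"), 1e-8)
  expect_error(joint_diagonalize(list(A, diag(4))), "dimension")
})

test_that("SOBI separates sinusoids mixed by a random matrix", {
  fs <- 200; t <- seq(0, 60 - 1 / fs, by = 1 / fs)
  set.seed(13)
  S_true <- rbind(sin(2 * pi * 1.5 * t), sin(2 * pi * 10 * t + 1))
  A <- matrix(c(1.2, 0.4, -0.3, 0.9), 2)
  X <- A %*% S_true
  m <- sobi_unmix(X, lags = 1:40, fs = fs)
  cors <- abs(cor(t(m$sources), t(S_true)))
  expect_true(all(apply(cors, 2, max) > 0.99))
  ## reconstruction property of the retained subspace
  expect_lt(max(abs(m$mixing %*% m$sources -
                      (X - rowMeans(X)))), 1e-6)
})

test_that("white independent channels give a signed-permutation gain matrix", {
  set.seed(14)
  ## channels with distinct lagged structure but unit variance
  n <- 20000
  ar <- stats::filter(rnorm(n), 0.9, "recursive"); ar <- ar / sd(ar)
  ma <- stats::filter(rnorm(n), rep(1, 5)); ma[is.na(ma)] <- 0
  ma <- ma / sd(ma)
  X <- rbind(as.numeric(ar), as.numeric(ma))
  m <- sobi_unmix(X, lags = 1:20)
  G <- m$unmixing %*% diag(1, 2)  # sources are (near) the channels
  ## each source loads on exactly one channel
  loading <- abs(G) / apply(abs(G), 1, max)
  expect_true(all(rowSums(loading > 0.2) == 1))
})

test_that("rank-deficient input takes the reduced-rank path without crashing", {
  set.seed(15)
  x <- rnorm(5000)
  X <- rbind(x, 2 * x, rnorm(5000))  # rank 2
  expect_warning(m <- sobi_unmix(X, lags = 1:10), "rank-deficient")
  expect_equal(m$rank, 2)
  expect_error(sobi_unmix(rbind(c(NaN, rnorm(999)), rnorm(1000)),
                          lags = 1:5), "non-finite")
})

test_that("stimulation-frequency sources are flagged, noise is not", {
  fs <- 500; t <- seq(0, 120 - 1 / fs, by = 1 / fs)
  set.seed(16)
  m <- list(sources = rbind(sin(2 * pi * 1.5 * t), rnorm(length(t))))
  m2 <- identify_ac_components(m, fs, 1.5)
  expect_true(m2$ac_flags[1])
  expect_false(m2$ac_flags[2])
  expect_error(identify_ac_components(m, fs, 400), "Nyquist")
})

test_that("DFT subtraction removes a stationary sinusoid near-exactly", {
  fs <- 1000; t <- seq(0, 40 - 1 / fs, by = 1 / fs)
  x <- 3 * cos(2 * pi * 1.5 * t + 0.4)
  y <- dft_subtract(x, fs, 1.5)
  expect_lt(sqrt(mean(y^2)) / sqrt(mean(x^2)), 1e-3)
  expect_equal(attr(y, "amplitude"), 3, tolerance = 1e-6)
  expect_error(dft_subtract(x, fs, 0), "positive")
})

test_that("DFT subtraction preserves an evoked train riding the sinusoid", {
  fs <- 1000; dur <- 40
  t <- seq(0, dur - 1 / fs, by = 1 / fs)
  wave <- evoked_kernel(seq(0, 250), 0.8, 1.2)
  clean <- rep(0, length(t))
  for (o in seq(1, dur - 1, by = 1 / 2.3))
    clean[round(o * fs) + seq_along(wave)] <- wave
  y <- dft_subtract(clean + 5 * cos(2 * pi * 1.5 * t), fs, 1.5)
  expect_gt(cor(as.numeric(y), clean), 0.99)
})

test_that("artifact removal attenuates 1.5 Hz and preserves the evoked LFP", {
  gs <- small_pair()
  cleaned <- remove_ac_artifact(filter_lfp(gs$flash_ac))
  qc <- attr(cleaned, "artifact_qc")
  expect_true(all(qc$attenuation_db >= 30))
  ## cleaned power at 1.5 Hz within 3 dB of the Flash condition's
  flash_f <- filter_lfp(gs$flash)
  fs <- cleaned$fs_lfp
  plat <- seq(round(35 * fs), round(53 * fs))
  p_cl <- mean(vapply(1:23, function(i)
    lamtacs:::power_at(cleaned$lfp_signals[i, plat], fs, 1.5), numeric(1)))
  p_fl <- mean(vapply(1:23, function(i)
    lamtacs:::power_at(flash_f$lfp_signals[i, plat], fs, 1.5), numeric(1)))
  expect_lt(abs(10 * log10(p_cl / p_fl)), 3)
  ## what was removed is (per contact) a pure stimulation sinusoid
  raw <- filter_lfp(gs$flash_ac)
  removed <- raw$lfp_signals[10, plat] - cleaned$lfp_signals[10, plat]
  fit <- lamtacs:::sinusoid_fit(removed, fs, 1.5)
  resid <- removed - (fit$a * cos(2 * pi * 1.5 * (seq_along(plat) - 1) / fs) +
                        fit$b * sin(2 * pi * 1.5 * (seq_along(plat) - 1) / fs))
  expect_lt(sd(resid), 0.02 * sd(removed))
})

test_that("wrong condition and artifact-free input follow their contracts", {
  gs <- small_pair()
  expect_error(remove_ac_artifact(gs$flash), "FLASH_AC")
  gs0 <- generate_session(synth_config(duration_s = 70,
                                       ac_amplitude_scale = 0, seed = 21))
  f0 <- filter_lfp(gs0$flash_ac)
  expect_warning(out <- remove_ac_artifact(f0), "unchanged")
  expect_identical(out$lfp_signals, f0$lfp_signals)
})
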