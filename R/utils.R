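#' @keywords internal
"_PACKAGE"

## Angle helpers. Package convention: angles exposed in degrees, cosine
## convention (0 deg = oscillation peak, +/-180 = trough, -90 = rising
## zero-crossing); radians only inside computations.

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Wrap angles in degrees to (-180, 180]
#'
#' @param x numeric vector of angles in degrees.
#' @return angles mapped into the half-open interval (-180, 180].
#' @export
wrap_deg <- function(x) {
  y <- (x + 180) %% 360 - 180
  y[y == -180] <- 180
  y
}

## Circular absolute difference in degrees, in [0, 180].
circ_diff_deg <- function(a, b) abs(wrap_deg(a - b))

#' Analytic signal via the FFT
#'
#' Returns the complex analytic signal whose angle is the instantaneous
#' phase under the cosine convention (a pure cosine maps to unit phasors
#' with zero angle at its peaks).
#'
#' @param x real numeric vector.
#' @return complex vector of the same length.
#' @export
analytic_signal <- function(x) {
  n <- length(x)
  stopifnot(n > 2)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

## Robust noise SD: median(|x|)/0.6745, the normal-consistent MAD-type
## estimate used to set spike-detection thresholds.
#' Robust noise standard deviation
#'
#' Estimates the noise SD of a signal as `median(|x|) / 0.6745`, which is
#' consistent for the SD of zero-mean Gaussian noise and insensitive to
#' sparse large events such as spikes.
#'
#' @param x numeric vector.
#' @return scalar noise SD estimate.
#' @export
robust_noise_sd <- function(x) stats::median(abs(x)) / 0.6745

## Single-frequency DFT amplitude/phase of a real signal: least-squares
## fit of a*cos + b*sin at f0 (exact DFT bin when f0*n/fs is integer).
sinusoid_fit <- function(x, fs, f0, idx = seq_along(x)) {
  t <- (idx - 1) / fs
  c_ <- cos(2 * pi * f0 * t); s_ <- sin(2 * pi * f0 * t)
  M <- cbind(c_, s_)
  ab <- stats::.lm.fit(M, x[idx])$coefficients
  list(a = ab[1], b = ab[2],
       amplitude = sqrt(sum(ab^2)),
       phase_deg = wrap_deg(rad2deg(atan2(-ab[2], ab[1]))))
}

## Power (mean squared amplitude) of x at frequency f0 via the fitted
## sinusoid; used for attenuation bookkeeping in dB.
power_at <- function(x, fs, f0) {
  fit <- sinusoid_fit(x, fs, f0)
  fit$amplitude^2 / 2
}

## Stage logging to stderr: auditable runs without polluting stdout.
log_stage <- function(stage, ...) {
  msg <- paste0("[", stage, "] ", paste0(..., collapse = ""))
  message(msg)
}

## Derive a bounded child seed from a master seed and a stream index;
## keeps every derived seed a valid 32-bit integer.
derive_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 48271 + 1009 * stream) %% 2147483647)
}

## Pink (1/f) noise by spectral shaping: flat-phase white spectrum scaled
## by 1/sqrt(f), unit-SD normalized.
pink_noise <- function(n, fs) {
  nf <- floor(n / 2)
  f <- seq_len(nf) * fs / n
  amp <- 1 / sqrt(f)
  ph <- stats::runif(nf, -pi, pi)
  spec <- complex(modulus = amp, argument = ph)
  full <- complex(real = numeric(n))
  full[2:(nf + 1)] <- spec
  if (n %% 2 == 0) {
    full[nf + 1] <- complex(real = Mod(full[nf + 1]))  # Nyquist bin real
    full[seq(n, nf + 2)] <- Conj(full[2:nf])
  } else {
    full[seq(n, nf + 2)] <- Conj(full[2:(nf + 1)])
  }
  x <- Re(stats::fft(full, inverse = TRUE))
  x / stats::sd(x)
}
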