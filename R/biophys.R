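## Stimulation biophysics: the voltage and electric-field depth profiles
## along the probe, and the stimulation phase at each stimulus onset.

#' Extract the narrowband stimulation waveform
#'
#' Band-passes each contact to 0.5-2 Hz with a 4th-order zero-phase
#' Butterworth and divides by the acquisition gain, returning the true
#' (mV) stimulation potential at the 1 kHz analysis rate. The filter is
#' applied on an anti-aliased decimated copy (the band sits far below
#' the raw Nyquist, where a direct transfer-function design is
#' ill-conditioned) and the band-limited result is spline-interpolated
#' back to 1 kHz; for content below 2 Hz this is exact to well under 1%.
#'
#' @param session a `recording_session` (`FLASH_AC`, or any condition
#'   when `allow_virtual` for control analyses).
#' @param cfg an [analysis_config()].
#' @param allow_virtual permit non-stimulation sessions.
#' @return matrix `[n_contacts x n_samples_1kHz]`, true mV.
#' @export
extract_ac_waveform <- function(session, cfg = analysis_config(),
                                allow_virtual = FALSE) {
  validate_session(session)
  if (!allow_virtual && session$condition != "FLASH_AC")
    stop("narrowband extraction expects the FLASH_AC condition")
  fs <- session$fs_lfp
  f0 <- cfg$ac_f0_hz
  if (ncol(session$lfp_signals) / fs < 10 / f0)
    stop("record shorter than 10 cycles of the stimulation frequency")
  ## anti-alias then decimate to ~100 Hz, narrowband filter, interp to 1 kHz
  fs_nb <- 100
  dec <- max(1, floor(fs / fs_nb))
  fs_d <- fs / dec
  lp <- signal::butter(4, min(0.8, (fs_d * 0.4) / (fs / 2)), type = "low")
  nb <- signal::butter(4, cfg$ac_band_hz / (fs_d / 2), type = "pass")
  n <- ncol(session$lfp_signals)
  t_d <- (seq(1, n, by = dec) - 1) / fs
  t_out <- seq(0, (n - 1) / fs, by = 1 / cfg$fs_target)
  out <- matrix(0, nrow(session$lfp_signals), length(t_out))
  for (i in seq_len(nrow(out))) {
    x <- signal::filtfilt(signal::Arma(lp$b, lp$a), session$lfp_signals[i, ])
    xd <- x[seq(1, n, by = dec)]
    xn <- signal::filtfilt(signal::Arma(nb$b, nb$a), xd)
    out[i, ] <- stats::spline(t_d, xn, xout = t_out)$y
  }
  out / session$gain
}

#' Electric field from a voltage depth profile
#'
#' Numerical gradient of the per-contact voltage amplitudes along the
#' probe: central differences at interior contacts, one-sided at the
#' ends. mV over mm gives V/m directly.
#'
#' @param voltage_profile per-contact voltage amplitudes, mV.
#' @param spacing_mm inter-contact spacing, mm.
#' @return per-contact field, V/m.
#' @export
compute_efield <- function(voltage_profile, spacing_mm) {
  v <- as.numeric(voltage_profile)
  nc <- length(v)
  if (nc < 3) stop("need at least 3 contacts")
  if (spacing_mm <= 0) stop("spacing must be positive")
  e <- numeric(nc)
  e[1] <- (v[2] - v[1]) / spacing_mm
  e[nc] <- (v[nc] - v[nc - 1]) / spacing_mm
  e[2:(nc - 1)] <- (v[3:nc] - v[1:(nc - 2)]) / (2 * spacing_mm)
  e
}

#' Dominant-frequency amplitude and phase of a signal
#'
#' Finds the peak-power FFT frequency, then re-evaluates amplitude and
#' cosine-convention phase by a least-squares sinusoid fit over an
#' integer number of cycles of that frequency (rejecting spectral
#' leakage from a non-integer record length).
#'
#' @param x numeric time series.
#' @param fs sampling rate, Hz.
#' @param f_min ignore frequencies below this when picking the peak.
#' @return list `amplitude`, `phase_deg`, `f_peak`.
#' @export
extract_amp_phase <- function(x, fs, f_min = 0.25) {
  n <- length(x)
  if (all(x == 0)) stop("all-zero signal: phase undefined")
  ## peak picking on a power-of-two prefix (prime lengths make the DFT
  ## quadratic); the amplitude/phase fit below still uses the full record
  nfft <- 2^floor(log2(n))
  freqs <- (seq_len(nfft) - 1) * fs / nfft
  P <- Mod(stats::fft(x[seq_len(nfft)] - mean(x[seq_len(nfft)])))^2
  sel <- freqs > f_min & freqs <= fs / 2
  f_coarse <- freqs[sel][which.max(P[sel])]
  if (n < 4 * fs / f_coarse)
    stop("record shorter than 4 cycles of the peak frequency")
  ## refine the bin-quantized peak by maximizing the fitted amplitude
  df <- fs / nfft
  f_peak <- stats::optimize(function(f) sinusoid_fit(x, fs, f)$amplitude,
                            c(max(f_min, f_coarse - df), f_coarse + df),
                            maximum = TRUE, tol = df * 1e-4)$maximum
  n_cyc <- floor((n / fs) * f_peak)
  n_fit <- round(n_cyc * fs / f_peak)
  fit <- sinusoid_fit(x, fs, f_peak, idx = seq_len(min(n_fit, n)))
  list(amplitude = fit$amplitude, phase_deg = fit$phase_deg, f_peak = f_peak)
}

#' Stimulation voltage and field profile along the probe
#'
#' Per-contact amplitude and phase at the dominant (stimulation)
#' frequency of the narrowband waveform, measured over the stimulation
#' plateau, plus the numerical-gradient electric field.
#'
#' @param ac narrowband matrix from [extract_ac_waveform()] (true mV,
#'   1 kHz).
#' @param session the source `recording_session` (for spacing and ramps).
#' @param cfg an [analysis_config()].
#' @return data frame `contact, depth_mm, voltage_mV, efield_V_per_m,
#'   phase_deg` with attribute `dominant_frequency_hz`.
#' @export
field_profile <- function(ac, session, cfg = analysis_config()) {
  fs <- cfg$fs_target
  n <- ncol(ac)
  t <- (seq_len(n) - 1) / fs
  plat <- t > session$ramp_s & t < n / fs - session$ramp_s
  amps <- numeric(nrow(ac)); phs <- numeric(nrow(ac)); fpk <- numeric(nrow(ac))
  for (i in seq_len(nrow(ac))) {
    ap <- extract_amp_phase(ac[i, plat], fs)
    amps[i] <- ap$amplitude; phs[i] <- ap$phase_deg; fpk[i] <- ap$f_peak
  }
  ef <- compute_efield(amps, session$contact_spacing_mm)
  out <- data.frame(contact = seq_len(nrow(ac)),
                    depth_mm = (seq_len(nrow(ac)) - 1) *
                      session$contact_spacing_mm,
                    voltage_mV = amps, efield_V_per_m = ef, phase_deg = phs)
  attr(out, "dominant_frequency_hz") <- stats::median(fpk)
  out
}

#' Stimulation phase at each stimulus onset
#'
#' Instantaneous phase of the narrowband waveform (analytic-signal
#' angle, cosine convention: 0 deg at the artifact peak, -90 deg on the
#' rising zero-crossing) sampled at each onset. Onsets within one
#' stimulation cycle of the record edges are marked invalid.
#'
#' @param ac single-contact narrowband series (1 kHz).
#' @param onsets_s onset times, s.
#' @param cfg an [analysis_config()].
#' @return a `phase_labels` data frame: `trial, phase_deg, valid` with
#'   attribute `method = "hilbert"`.
#' @export
phase_at_onsets <- function(ac, onsets_s, cfg = analysis_config()) {
  fs <- cfg$fs_target
  n <- length(ac)
  guard <- 1 / cfg$ac_f0_hz
  phase <- rad2deg(Arg(analytic_signal(ac)))
  smp <- round(onsets_s * fs) + 1
  valid <- onsets_s >= guard & onsets_s <= n / fs - guard &
    smp >= 1 & smp <= n
  out <- data.frame(trial = seq_along(onsets_s),
                    phase_deg = ifelse(valid, wrap_deg(phase[pmin(pmax(smp, 1),
                                                                  n)]),
                                       NA_real_),
                    valid = valid)
  attr(out, "method") <- "hilbert"
  class(out) <- c("phase_labels", class(out))
  out
}

#' Virtual stimulation phase labels for the no-stimulation control
#'
#' Labels each onset against a fictitious cosine at `f0` starting at
#' record time zero: `phase = wrap(360 * f0 * t_onset)`. Used to run the
#' phase-dependency analysis on the Flash condition as a negative
#' control.
#'
#' @param session a `recording_session` with `condition == "FLASH"`.
#' @param f0 virtual frequency, Hz.
#' @return a `phase_labels` data frame (attribute `method = "virtual"`).
#' @export
virtual_ac_labels <- function(session, f0 = 1.5) {
  validate_session(session)
  if (session$condition != "FLASH")
    stop("virtual labels apply to the FLASH condition only")
  out <- data.frame(trial = seq_along(session$stim_onsets_s),
                    phase_deg = wrap_deg(360 * f0 * session$stim_onsets_s),
                    valid = TRUE)
  attr(out, "method") <- "virtual"
  class(out) <- c("phase_labels", class(out))
  out
}
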