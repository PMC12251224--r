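## Synthetic laminar-session generator. Emulates the study conditions:
## a 23-contact probe (0.1 mm spacing) bracketing all cortical layers,
## flash-evoked LFPs at 2.3 Hz whose P1 (~75 ms) / N1 (~120 ms)
## amplitudes grow with depth, a 1.5 Hz stimulation artifact far larger
## than the LFP whose depth gradient peaks in layers 2/3, optional
## phase-dependent modulation of the evoked components in deep layers,
## pink + 60 Hz line noise, x10 acquisition gain, and an optional
## wideband stream carrying Poisson multi-unit spikes.

LAYER_ORDER <- c("OUTSIDE", "L1", "L23", "L4AB", "L4C", "L56", "WM")

.layer_counts_default <- c(OUTSIDE = 3, L1 = 2, L23 = 5, L4AB = 2,
                           L4C = 4, L56 = 4, WM = 3)

## Expand per-layer contact counts into a label vector along the probe.
layer_labels_from_counts <- function(counts) {
  counts <- counts[LAYER_ORDER[LAYER_ORDER %in% names(counts)]]
  rep(names(counts), counts)
}

## Per-layer template value ranges, linearly interpolated within a layer.
.profile_from_layers <- function(labels, ranges) {
  out <- numeric(length(labels))
  for (lab in unique(labels)) {
    idx <- which(labels == lab)
    r <- ranges[[lab]]
    out[idx] <- if (length(r) == 1) rep(r, length(idx)) else
      seq(r[1], r[2], length.out = length(idx))
  }
  out
}

#' Synthetic session configuration
#'
#' Defaults describe the emulated recording: 23 contacts at 0.1 mm,
#' LFP stream at 2 kHz, 2.3 Hz flashes, 1.5 Hz stimulation with 30 s
#' cosine ramps, evoked depth profile monotone increasing toward the deep
#' layers, stimulation-field depth gradient peaking in layers 2/3
#' (~2.5 V/m) over a mean potential ~50x the deep-layer evoked amplitude,
#' and unimodal phase-dependent modulation (depth 0.3, preferred phase
#' -90 deg, i.e., the rising phase) of the deep-layer components.
#'
#' @param duration_s total record duration including ramps, s.
#' @param layer_counts named contact counts per layer label (in probe
#'   order `OUTSIDE, L1, L23, L4AB, L4C, L56, WM`); must sum to
#'   `n_contacts`.
#' @param mod_mode `"none"`, `"unimodal"` or `"axial"` modulation of the
#'   evoked amplitudes by the stimulation phase at flash onset.
#' @param mod_depth modulation depth `m` in `[0, 1)`.
#' @param mod_phi_pref_deg preferred phase of the P1 modulation, degrees.
#' @param mod_n1_offset_deg phase offset of the N1 modulation relative to
#'   P1 (180 = opposite preference, as for a driving-force mechanism).
#' @param mod_layers layer labels whose contacts are modulated.
#' @param ac_amplitude_scale scalar on the stimulation potential profile
#'   (0 disables the artifact entirely).
#' @param include_wideband generate the 20 kHz spike-band stream?
#' @param seed master seed; noise streams for the two conditions and the
#'   spike trains are derived from it in a documented order.
#' @param ... overrides for any other listed default.
#' @return a list of class `synth_config`.
#' @export
synth_config <- function(duration_s = 240, layer_counts = .layer_counts_default,
                         mod_mode = "unimodal", mod_depth = 0.3,
                         mod_phi_pref_deg = -90, mod_n1_offset_deg = 180,
                         mod_layers = c("L4AB", "L4C", "L56"),
                         ac_amplitude_scale = 1, include_wideband = FALSE,
                         seed = 1L, ...) {
  cfg <- list(
    n_contacts = 23L, spacing_mm = 0.1, fs_lfp = 2000, fs_wideband = 20000,
    duration_s = duration_s, flash_rate_hz = 2.3, ac_hz = 1.5, ramp_s = 30,
    gain = 10,
    layer_counts = layer_counts,
    ## evoked component magnitudes (mV, true units) by layer
    p1_ranges = list(OUTSIDE = c(0.008, 0.01), L1 = c(0.015, 0.02),
                     L23 = c(0.025, 0.04), L4AB = c(0.045, 0.05),
                     L4C = c(0.055, 0.07), L56 = c(0.075, 0.08), WM = 0.08),
    n1_gain = 1.8,                      # N1 magnitude = n1_gain * P1
    p1_latency_ms = 75, p1_sigma_ms = 8,
    n1_latency_ms = 120, n1_sigma_ms = 12,
    ## early layer-4C input sink: depth-localized negative deflection
    sink_amp_mV = 0.05, sink_latency_ms = 45, sink_sigma_ms = 6,
    sink_depth_sigma_contacts = 1.2,
    ## stimulation field truth (V/m) by layer; potential = cumulative sum
    efield_ranges = list(OUTSIDE = 0.1, L1 = c(0.8, 1.5),
                         L23 = c(2.2, 2.5), L4AB = c(1.5, 1.2),
                         L4C = c(0.9, 0.6), L56 = c(0.5, 0.35), WM = 0.3),
    potential_offset_mV = 5,
    ac_amplitude_scale = ac_amplitude_scale,
    mod_mode = mod_mode, mod_depth = mod_depth,
    mod_phi_pref_deg = mod_phi_pref_deg,
    mod_n1_offset_deg = mod_n1_offset_deg, mod_layers = mod_layers,
    ## noise (true units, mV)
    pink_sd_mV = 0.02, common_mode_frac = 0.2, line60_mV = 0.005,
    ## multi-unit stream
    include_wideband = include_wideband,
    mua_base_rates = c(OUTSIDE = 0.5, L1 = 1, L23 = 5, L4AB = 12,
                       L4C = 15, L56 = 20, WM = 0.5),
    mua_evoked_gain = 4, mua_evoked_window_ms = c(10, 150),
    wb_noise_sd_mV = 0.005, spike_amp_mV = 0.05, spike_dur_ms = 1,
    seed = as.integer(seed)
  )
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown synth_config field(s): ",
                        paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  if (sum(cfg$layer_counts) != cfg$n_contacts)
    stop("layer_counts must sum to n_contacts")
  if (cfg$mod_depth < 0 || cfg$mod_depth >= 1)
    stop("mod_depth must be in [0, 1)")
  if (!cfg$mod_mode %in% c("none", "unimodal", "axial"))
    stop("mod_mode must be none, unimodal or axial")
  class(cfg) <- "synth_config"
  cfg
}

#' Flash-evoked LFP kernel
#'
#' Difference of two Gaussians: a positive P1 lobe peaking at 75 ms
#' (sigma 8 ms) and a negative N1 lobe at 120 ms (sigma 12 ms); zero
#' before stimulus onset.
#'
#' @param t_ms time axis in ms relative to stimulus onset.
#' @param p1_amp,n1_amp nonnegative magnitudes of the two lobes.
#' @param p1_lat,n1_lat,p1_sig,n1_sig peak latencies and widths, ms.
#' @return numeric waveform on `t_ms`.
#' @export
evoked_kernel <- function(t_ms, p1_amp, n1_amp, p1_lat = 75, n1_lat = 120,
                          p1_sig = 8, n1_sig = 12) {
  stopifnot(is.finite(p1_amp), is.finite(n1_amp))
  k <- p1_amp * exp(-(t_ms - p1_lat)^2 / (2 * p1_sig^2)) -
       n1_amp * exp(-(t_ms - n1_lat)^2 / (2 * n1_sig^2))
  k[t_ms < 0] <- 0
  k
}

## Cosine on/off ramp envelope for the stimulation current.
ramp_envelope <- function(t, duration_s, ramp_s) {
  env <- rep(1, length(t))
  up <- t < ramp_s
  env[up] <- 0.5 * (1 - cos(pi * t[up] / ramp_s))
  dn <- t > duration_s - ramp_s
  env[dn] <- 0.5 * (1 - cos(pi * (duration_s - t[dn]) / ramp_s))
  env
}

## Per-trial modulation factors from the deterministic modulation law.
modulation_factors <- function(phases_deg, mode, m, phi_pref_deg) {
  if (mode == "none" || m == 0) return(rep(1, length(phases_deg)))
  d <- deg2rad(phases_deg - phi_pref_deg)
  if (mode == "unimodal") 1 + m * cos(d) else 1 + m * cos(2 * d)
}

.make_noise <- function(n_contacts, n, fs, cfg) {
  common <- pink_noise(n, fs)
  line_phi <- stats::runif(1, -pi, pi)
  line <- cfg$line60_mV * sin(2 * pi * 60 * seq(0, by = 1 / fs,
                                                length.out = n) + line_phi)
  out <- matrix(0, n_contacts, n)
  for (i in seq_len(n_contacts)) {
    out[i, ] <- cfg$pink_sd_mV *
      (pink_noise(n, fs) + cfg$common_mode_frac * common) /
      sqrt(1 + cfg$common_mode_frac^2) + line
  }
  out
}

## Clean (noise- and artifact-free) evoked record builder, true units.
.build_clean_lfp <- function(cfg, onsets_s, fP1, fN1, mod_contact) {
  fs <- cfg$fs_lfp
  n <- round(cfg$duration_s * fs)
  labels <- layer_labels_from_counts(cfg$layer_counts)
  p1 <- .profile_from_layers(labels, cfg$p1_ranges)
  n1 <- cfg$n1_gain * p1
  l4c <- which(labels == "L4C")
  sink_depth <- cfg$sink_amp_mV *
    exp(-(seq_along(labels) - mean(l4c))^2 /
          (2 * cfg$sink_depth_sigma_contacts^2))
  klen <- round(0.3 * fs)
  kt <- seq(0, by = 1000 / fs, length.out = klen)
  K1 <- exp(-(kt - cfg$p1_latency_ms)^2 / (2 * cfg$p1_sigma_ms^2))
  K2 <- exp(-(kt - cfg$n1_latency_ms)^2 / (2 * cfg$n1_sigma_ms^2))
  K3 <- exp(-(kt - cfg$sink_latency_ms)^2 / (2 * cfg$sink_sigma_ms^2))
  X <- matrix(0, cfg$n_contacts, n)
  for (k in seq_along(onsets_s)) {
    i0 <- round(onsets_s[k] * fs) + 1
    idx <- i0:min(i0 + klen - 1, n)
    kk <- seq_along(idx)
    p1k <- p1 * ifelse(mod_contact, fP1[k], 1)
    n1k <- n1 * ifelse(mod_contact, fN1[k], 1)
    X[, idx] <- X[, idx] + outer(p1k, K1[kk]) - outer(n1k, K2[kk]) -
      outer(sink_depth, K3[kk])
  }
  list(X = X, p1_profile = p1, n1_profile = n1, sink_depth = sink_depth,
       labels = labels)
}

## Wideband stream: volume-conducted LFP content + white noise + spikes.
.build_wideband <- function(cfg, lfp_true, onsets_s, labels, seed) {
  fs <- cfg$fs_wideband
  n <- round(cfg$duration_s * fs)
  t_lfp <- seq(0, by = 1 / cfg$fs_lfp, length.out = ncol(lfp_true))
  t_wb <- seq(0, by = 1 / fs, length.out = n)
  tpl_n <- round(cfg$spike_dur_ms / 1000 * fs)
  tpl <- cfg$spike_amp_mV * sin(2 * pi * seq(0, 1, length.out = tpl_n))
  rates <- cfg$mua_base_rates[labels]
  ew <- cfg$mua_evoked_window_ms / 1000
  set.seed(seed)
  W <- matrix(stats::rnorm(cfg$n_contacts * n, sd = cfg$wb_noise_sd_mV),
              cfg$n_contacts, n)
  spikes <- vector("list", cfg$n_contacts)
  for (i in seq_len(cfg$n_contacts)) {
    W[i, ] <- W[i, ] + stats::approx(t_lfp, lfp_true[i, ], xout = t_wb,
                                     rule = 2)$y
    n_base <- stats::rpois(1, rates[i] * cfg$duration_s)
    st <- stats::runif(n_base, 0, cfg$duration_s)
    n_ev <- stats::rpois(length(onsets_s),
                         rates[i] * (cfg$mua_evoked_gain - 1) * diff(ew))
    for (k in seq_along(onsets_s)) {
      if (n_ev[k] > 0)
        st <- c(st, onsets_s[k] + stats::runif(n_ev[k], ew[1], ew[2]))
    }
    st <- sort(st[st < cfg$duration_s - cfg$spike_dur_ms / 1000])
    for (s0 in st) {
      i0 <- round(s0 * fs) + 1
      idx <- i0:(i0 + tpl_n - 1)
      W[i, idx] <- W[i, idx] + tpl
    }
    spikes[[i]] <- st
  }
  list(W = W, spikes = spikes)
}

#' Generate a paired Flash / Flash+AC synthetic session
#'
#' Builds two recordings sharing the same evoked structure and stimulus
#' schedule: the Flash condition (no stimulation) and the Flash+AC
#' condition (sinusoidal artifact plus optional phase-dependent evoked
#' modulation). Noise realizations for the two conditions come from
#' independent streams derived from the master seed (stream order:
#' 1 = Flash noise, 2 = Flash+AC noise, 3 = Flash spikes, 4 = Flash+AC
#' spikes). The returned ground truth carries every injected parameter
#' plus the per-trial true onset phases and modulation factors.
#'
#' @param cfg a [synth_config()].
#' @return list with `flash`, `flash_ac` (both [recording_session()]) and
#'   `truth` (class `ground_truth`).
#' @export
generate_session <- function(cfg = synth_config()) {
  stopifnot(inherits(cfg, "synth_config"))
  fs <- cfg$fs_lfp
  n <- round(cfg$duration_s * fs)
  t <- seq(0, by = 1 / fs, length.out = n)
  t0 <- cfg$ramp_s + 0.2
  t_end <- cfg$duration_s - cfg$ramp_s - 0.35
  if (t_end <= t0) stop("duration too short for any trial after the ramps")
  onsets <- seq(t0, t_end, by = 1 / cfg$flash_rate_hz)
  if (!length(onsets)) stop("duration too short for any trial after the ramps")

  ## true phase of the stimulation cosine at each onset
  phases <- wrap_deg(360 * cfg$ac_hz * onsets)
  fP1 <- modulation_factors(phases, cfg$mod_mode, cfg$mod_depth,
                            cfg$mod_phi_pref_deg)
  fN1 <- modulation_factors(phases, cfg$mod_mode, cfg$mod_depth,
                            cfg$mod_phi_pref_deg + cfg$mod_n1_offset_deg)

  labels <- layer_labels_from_counts(cfg$layer_counts)
  mod_contact <- labels %in% cfg$mod_layers
  efield <- .profile_from_layers(labels, cfg$efield_ranges)
  ## potential (mV) whose numerical gradient reproduces the field truth:
  ## V/m * mm = mV
  potential <- cfg$potential_offset_mV +
    cumsum(c(0, (efield[-1] + efield[-length(efield)]) / 2 * cfg$spacing_mm))
  potential <- potential * cfg$ac_amplitude_scale
  efield_scaled <- efield * cfg$ac_amplitude_scale

  ## Flash condition: evoked (unmodulated) + noise
  base <- .build_clean_lfp(cfg, onsets, fP1 = rep(1, length(onsets)),
                           fN1 = rep(1, length(onsets)), mod_contact)
  set.seed(derive_seed(cfg$seed, 1L))
  flash_sig <- cfg$gain * (base$X + .make_noise(cfg$n_contacts, n, fs, cfg))

  ## Flash+AC: modulated evoked + ramped artifact + independent noise
  mod <- .build_clean_lfp(cfg, onsets, fP1, fN1, mod_contact)
  env <- ramp_envelope(t, cfg$duration_s, cfg$ramp_s)
  carrier <- cos(2 * pi * cfg$ac_hz * t) * env
  artifact <- outer(potential, rep(1, n)) * rep(carrier, each = cfg$n_contacts)
  set.seed(derive_seed(cfg$seed, 2L))
  ac_sig <- cfg$gain *
    (mod$X + artifact + .make_noise(cfg$n_contacts, n, fs, cfg))

  wb_flash <- wb_ac <- NULL
  spikes_flash <- spikes_ac <- NULL
  if (cfg$include_wideband) {
    bf <- .build_wideband(cfg, base$X, onsets, labels,
                          derive_seed(cfg$seed, 3L))
    ba <- .build_wideband(cfg, mod$X + artifact, onsets, labels,
                          derive_seed(cfg$seed, 4L))
    wb_flash <- cfg$gain * bf$W; spikes_flash <- bf$spikes
    wb_ac <- cfg$gain * ba$W;    spikes_ac <- ba$spikes
  }

  flash <- recording_session(flash_sig, fs, onsets, "FLASH",
                             wideband_signals = wb_flash,
                             fs_wideband = if (cfg$include_wideband)
                               cfg$fs_wideband else NULL,
                             contact_spacing_mm = cfg$spacing_mm,
                             gain = cfg$gain, ac_frequency_hz = cfg$ac_hz,
                             ramp_s = cfg$ramp_s)
  flash_ac <- recording_session(ac_sig, fs, onsets, "FLASH_AC",
                                wideband_signals = wb_ac,
                                fs_wideband = if (cfg$include_wideband)
                                  cfg$fs_wideband else NULL,
                                contact_spacing_mm = cfg$spacing_mm,
                                gain = cfg$gain, ac_frequency_hz = cfg$ac_hz,
                                ramp_s = cfg$ramp_s)

  ## clean evoked average on the analysis grid (1 kHz, -50..250 ms)
  t_ms <- -50:250
  K1 <- evoked_kernel(t_ms, 1, 0, cfg$p1_latency_ms, cfg$n1_latency_ms,
                      cfg$p1_sigma_ms, cfg$n1_sigma_ms)
  K2 <- -evoked_kernel(t_ms, 0, 1, cfg$p1_latency_ms, cfg$n1_latency_ms,
                       cfg$p1_sigma_ms, cfg$n1_sigma_ms)
  K3 <- exp(-(t_ms - cfg$sink_latency_ms)^2 / (2 * cfg$sink_sigma_ms^2))
  K3[t_ms < 0] <- 0
  p1eff <- mod$p1_profile * ifelse(mod_contact, mean(fP1), 1)
  n1eff <- mod$n1_profile * ifelse(mod_contact, mean(fN1), 1)
  clean_avg_ac <- outer(p1eff, K1) - outer(n1eff, K2) -
    outer(mod$sink_depth, K3)
  clean_avg_flash <- outer(mod$p1_profile, K1) - outer(mod$n1_profile, K2) -
    outer(mod$sink_depth, K3)

  truth <- structure(list(
    config = cfg, onsets_s = onsets, phases_deg = phases,
    fP1 = fP1, fN1 = fN1,
    layer_labels = labels, modulated_contacts = which(mod_contact),
    p1_profile_mV = mod$p1_profile, n1_profile_mV = mod$n1_profile,
    efield_V_per_m = efield_scaled, potential_mV = potential,
    clean_evoked_avg_flash = clean_avg_flash,
    clean_evoked_avg_flash_ac = clean_avg_ac,
    t_ms = t_ms,
    spike_times_flash = spikes_flash, spike_times_flash_ac = spikes_ac
  ), class = "ground_truth")
  ## per-trial true component amplitudes (pre-noise)
  P1 <- outer(rep(1, length(fP1)), mod$p1_profile)
  N1 <- outer(rep(1, length(fN1)), mod$n1_profile)
  P1[, mod_contact] <- outer(fP1, mod$p1_profile[mod_contact])
  N1[, mod_contact] <- outer(fN1, mod$n1_profile[mod_contact])
  truth$p1_amp_true <- P1
  truth$n1_amp_true <- N1
  list(flash = flash, flash_ac = flash_ac, truth = truth)
}
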