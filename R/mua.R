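## Multi-unit activity: spike-band filtering, threshold-crossing
## detection, peristimulus time histograms, phase-locked trial
## selection and firing-rate comparisons.

#' Spike-band filter of the wideband stream
#'
#' 300-5000 Hz Butterworth band-pass applied forward-reverse (zero
#' phase, so spike peak times are not shifted).
#'
#' @param session a `recording_session` with a wideband stream at
#'   `fs_wideband >= 20 kHz`.
#' @param cfg an [analysis_config()].
#' @return filtered matrix `[contacts x samples]`.
#' @export
filter_mua <- function(session, cfg = analysis_config()) {
  validate_session(session)
  if (is.null(session$wideband_signals))
    stop("session has no wideband stream")
  fs <- session$fs_wideband
  if (fs < 20000) stop("filter_mua expects fs_wideband >= 20 kHz")
  bp <- signal::butter(4, cfg$mua_band_hz / (fs / 2), type = "pass")
  .filtfilt_rows(session$wideband_signals, bp$b, bp$a)
}

#' Threshold-crossing spike detection
#'
#' Per contact, `threshold = alpha * median(|x|) / 0.6745` (the robust
#' Gaussian-noise SD estimate times the threshold factor, 3.5 by
#' default). An event is each upward crossing of `+threshold`; crossings
#' closer than the dead time (1 ms) are merged to the first. A
#' degenerate all-zero trace yields a zero threshold and no events.
#'
#' @param filtered spike-band matrix from [filter_mua()].
#' @param fs sampling rate of `filtered`, Hz.
#' @param alpha threshold factor (> 0).
#' @param dead_time_ms merge window for consecutive crossings.
#' @return a `spike_train_set`: per contact `spike_times_s`, plus
#'   `threshold`, `alpha`, `fs`.
#' @export
detect_spikes <- function(filtered, fs, alpha = 3.5, dead_time_ms = 1) {
  if (alpha <= 0) stop("alpha must be positive")
  if (ncol(filtered) < fs) stop("need at least 1 s of signal")
  dead <- round(dead_time_ms / 1000 * fs)
  thr <- apply(filtered, 1, function(x) alpha * robust_noise_sd(x))
  spikes <- vector("list", nrow(filtered))
  for (i in seq_len(nrow(filtered))) {
    if (thr[i] == 0) { spikes[[i]] <- numeric(0); next }
    x <- filtered[i, ]
    up <- which(x[-1] >= thr[i] & x[-length(x)] < thr[i]) + 1
    if (length(up) > 1) {
      keep <- c(TRUE, diff(up) > dead)
      up <- up[keep]
    }
    spikes[[i]] <- (up - 1) / fs
  }
  structure(list(spike_times_s = spikes, threshold = thr, alpha = alpha,
                 fs = fs),
            class = "spike_train_set")
}

#' Peristimulus time histogram per layer
#'
#' Spike counts in 10 ms bins over 0-250 ms after each onset, converted
#' to rates (spikes/s), averaged across trials and then across the
#' contacts of each layer. The per-trial, per-layer time-averaged rate
#' table is retained for the firing-rate comparisons.
#'
#' @param spikes a `spike_train_set`.
#' @param onsets_s stimulus onsets, s.
#' @param layers a `layer_map` data frame (one row per contact).
#' @param bin_ms PSTH bin width; must divide the window exactly.
#' @param window_ms analysis window, ms after onset.
#' @param which_layers layers to report.
#' @return a `psth`: `rates [layers x bins]` (spikes/s), `bin_edges_ms`,
#'   `trial_rates` (data frame `trial, layer, rate`).
#' @export
compute_psth <- function(spikes, onsets_s, layers, bin_ms = 10,
                         window_ms = c(0, 250),
                         which_layers = c("L1", "L23", "L4AB", "L4C",
                                          "L56")) {
  if (!length(onsets_s)) stop("need at least one onset")
  span <- diff(window_ms)
  n_bins <- span / bin_ms
  if (n_bins != round(n_bins)) stop("bin width must divide the window")
  edges <- seq(window_ms[1], window_ms[2], by = bin_ms)
  present <- which_layers[which_layers %in% layers$label]
  n_tr <- length(onsets_s)
  counts <- array(0, c(n_tr, nrow(layers), n_bins))
  for (i in seq_len(nrow(layers))) {
    st <- spikes$spike_times_s[[i]]
    if (!length(st)) next
    for (k in seq_len(n_tr)) {
      rel <- (st - onsets_s[k]) * 1000
      sel <- rel >= window_ms[1] & rel < window_ms[2]
      if (any(sel))
        counts[k, i, ] <- tabulate(
          floor((rel[sel] - window_ms[1]) / bin_ms) + 1, nbins = n_bins)
    }
  }
  rates <- matrix(0, length(present), n_bins,
                  dimnames = list(present, NULL))
  trial_rates <- NULL
  for (j in seq_along(present)) {
    idx <- which(layers$label == present[j])
    lay_counts <- counts[, idx, , drop = FALSE]
    rates[j, ] <- apply(lay_counts, 3, mean) / (bin_ms / 1000)
    tr <- apply(lay_counts, 1, mean) / (bin_ms / 1000)
    trial_rates <- rbind(trial_rates,
                         data.frame(trial = seq_len(n_tr),
                                    layer = present[j], rate = tr))
  }
  structure(list(rates = rates, bin_edges_ms = edges, bin_ms = bin_ms,
                 window_ms = window_ms, trial_rates = trial_rates),
            class = "psth")
}

#' Select trials phase-locked to the stimulation peak or trough
#'
#' Peak trials satisfy `|phi| <= window`; trough trials
#' `|wrap(phi - 180)| <= window` (default window 45 degrees).
#'
#' @param labels a `phase_labels` data frame.
#' @param target `"peak"` or `"trough"`.
#' @param window_deg half-width of the selection window, in (0, 90].
#' @return integer trial indices.
#' @export
select_phase_locked_trials <- function(labels, target = c("peak", "trough"),
                                       window_deg = 45) {
  target <- match.arg(target)
  if (window_deg <= 0 || window_deg > 90)
    stop("window_deg must be in (0, 90]")
  phi <- labels$phase_deg
  d <- if (target == "peak") circ_diff_deg(phi, 0) else
    circ_diff_deg(phi, 180)
  which(labels$valid & is.finite(phi) & d <= window_deg)
}

#' Compare firing rates between two trial sets
#'
#' Standard paired or unpaired two-sample t test (two-sided) on
#' per-trial rates.
#'
#' @param ratesA,ratesB per-trial rate vectors.
#' @param design `"paired"` or `"unpaired"`.
#' @return list `t, p_value, df, design`.
#' @export
compare_firing <- function(ratesA, ratesB, design = c("unpaired", "paired")) {
  design <- match.arg(design)
  if (length(ratesA) < 2 || length(ratesB) < 2)
    stop("need at least 2 trials per sample")
  if (design == "paired" && length(ratesA) != length(ratesB))
    stop("paired design requires equal lengths")
  ## degenerate zero-variance comparisons: no evidence of a difference
  degenerate <- if (design == "paired") all(ratesA == ratesB) else
    stats::sd(c(ratesA, ratesB)) == 0
  if (degenerate) {
    df <- if (design == "paired") length(ratesA) - 1 else
      length(ratesA) + length(ratesB) - 2
    return(list(t = 0, p_value = 1, df = df, design = design))
  }
  ht <- stats::t.test(ratesA, ratesB, paired = design == "paired",
                      var.equal = design == "unpaired")
  list(t = unname(ht$statistic), p_value = ht$p.value,
       df = unname(ht$parameter), design = design)
}
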