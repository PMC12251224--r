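## LFP-band conditioning and epoch-level preprocessing.

## RBJ biquad notch at f0 with quality factor Q, applied zero-phase.
notch_biquad <- function(f0, fs, Q) {
  w0 <- 2 * pi * f0 / fs
  alpha <- sin(w0) / (2 * Q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  list(b = b / a[1], a = a / a[1])
}

.filtfilt_rows <- function(X, b, a) {
  for (i in seq_len(nrow(X)))
    X[i, ] <- signal::filtfilt(signal::Arma(b = b, a = a), X[i, ])
  X
}

#' LFP-band filter and downsample to 1 kHz
#'
#' Applies the 4th-order Butterworth band-pass (0.5-100 Hz by default)
#' and a 60 Hz notch, both forward-reverse (zero phase, so evoked
#' latencies are not shifted; the effective magnitude roll-off doubles),
#' then decimates to the 1 kHz analysis rate.
#'
#' @param session a `recording_session` with `fs_lfp >= 2000`.
#' @param cfg an [analysis_config()].
#' @return a new `recording_session` at 1 kHz (band-limited content).
#' @export
filter_lfp <- function(session, cfg = analysis_config()) {
  validate_session(session)
  fs <- session$fs_lfp
  if (fs < 2000) stop("filter_lfp expects fs_lfp >= 2 kHz")
  dec <- fs / cfg$fs_target
  if (dec != round(dec))
    stop("fs_lfp (", fs, ") is not an integer multiple of ", cfg$fs_target,
         " Hz; resample the recording to a multiple of the target rate first")
  bp <- signal::butter(cfg$lfp_filter_order,
                       cfg$lfp_band_hz / (fs / 2), type = "pass")
  X <- .filtfilt_rows(session$lfp_signals, bp$b, bp$a)
  nt <- notch_biquad(cfg$notch_hz, fs, cfg$notch_q)
  X <- .filtfilt_rows(X, nt$b, nt$a)
  X <- X[, seq(1, ncol(X), by = dec), drop = FALSE]
  out <- session
  out$lfp_signals <- X
  out$fs_lfp <- cfg$fs_target
  log_stage("filter_lfp", sprintf("band %g-%g Hz, notch %g Hz, %g -> %g Hz",
            cfg$lfp_band_hz[1], cfg$lfp_band_hz[2], cfg$notch_hz, fs,
            cfg$fs_target))
  out
}

#' Segment a session into baseline-corrected epochs
#'
#' Cuts a fixed peri-stimulus window (default -50..250 ms inclusive at
#' 1 kHz, 301 samples) around every onset and subtracts the per-trial,
#' per-contact mean over the baseline (-50..0 ms, pre-onset samples).
#' Onsets too close to the record edges are dropped with a warning.
#'
#' @param session a `recording_session` at the 1 kHz analysis rate.
#' @param cfg an [analysis_config()].
#' @return an `epoch_set`: list with `data [trials x contacts x time]`,
#'   `t_ms`, `keep_mask`, `baseline_corrected`, `condition`, `trial_index`.
#' @export
epoch_and_baseline <- function(session, cfg = analysis_config()) {
  validate_session(session)
  fs <- session$fs_lfp
  if (fs != cfg$fs_target)
    stop("epoching expects the ", cfg$fs_target, " Hz analysis rate; ",
         "run filter_lfp first")
  win <- cfg$epoch_window_ms
  t_ms <- seq(win[1], win[2])
  n_t <- length(t_ms)
  n <- ncol(session$lfp_signals)
  onset_smp <- round(session$stim_onsets_s * fs) + 1
  first <- onset_smp + win[1]; last <- onset_smp + win[2]
  ok <- first >= 1 & last <= n
  if (any(!ok))
    warning(sum(!ok), " onset(s) too close to the record edge; dropped")
  onset_smp <- onset_smp[ok]
  n_trials <- length(onset_smp)
  if (!n_trials) stop("no onsets leave room for the epoch window")
  n_c <- nrow(session$lfp_signals)
  data <- array(NA_real_, c(n_trials, n_c, n_t))
  for (k in seq_len(n_trials))
    data[k, , ] <- session$lfp_signals[, (onset_smp[k] + win[1]):
                                          (onset_smp[k] + win[2])]
  bl <- t_ms >= cfg$baseline_ms[1] & t_ms < cfg$baseline_ms[2]
  bl_mean <- rowMeans(data[, , bl, drop = FALSE], dims = 2)
  data <- data - as.vector(bl_mean)  # recycles over the time dimension
  structure(list(data = data, t_ms = t_ms, baseline_corrected = TRUE,
                 keep_mask = rep(TRUE, n_trials),
                 condition = session$condition,
                 trial_index = which(ok)),
            class = "epoch_set")
}

#' Mark artifact trials by the across-trial +/-5 SD envelope
#'
#' For each contact and timepoint, the mean and SD over all trials define
#' an envelope `mean +/- k*SD` (k = 5); a trial is excluded iff any of
#' its samples falls strictly outside its envelope. Data are retained;
#' only `keep_mask` is updated. With `reject_pool = "per_trial_rms"` the
#' alternative pooling is used: a trial is excluded iff its RMS exceeds
#' the across-trial mean RMS + k*SD.
#'
#' @param epochs an `epoch_set` with at least 2 trials.
#' @param cfg an [analysis_config()].
#' @return the `epoch_set` with an updated `keep_mask`.
#' @export
reject_trials <- function(epochs, cfg = analysis_config()) {
  d <- epochs$data
  if (dim(d)[1] < 2) stop("trial rejection needs at least 2 trials")
  k <- cfg$reject_sd
  if (identical(cfg$reject_pool, "per_trial_rms")) {
    rms <- sqrt(apply(d^2, 1, mean))
    bad <- rms > mean(rms) + k * stats::sd(rms)
  } else {
    n_tr <- dim(d)[1]
    mu <- colMeans(d)                       # contacts x time
    sdv <- sqrt(pmax(colSums(d^2) - n_tr * mu^2, 0) / (n_tr - 1))
    lo <- mu - k * sdv; hi <- mu + k * sdv
    out <- sweep(d, c(2, 3), lo, "<") | sweep(d, c(2, 3), hi, ">")
    bad <- rowSums(matrix(out, n_tr)) > 0
  }
  epochs$keep_mask <- !bad
  log_stage("reject_trials", sprintf("%d/%d trials kept", sum(!bad),
                                     length(bad)))
  epochs
}

#' Extract P1 and N1 components per trial
#'
#' P1 is the maximum value and its latency inside 55-90 ms; N1 the
#' minimum and its latency inside 100-140 ms, per trial and per trace
#' (contact or layer). Ties break toward the earliest sample. N1 is
#' stored signed (<= 0 for a genuine negative deflection).
#'
#' @param epochs a baseline-corrected `epoch_set` (contacts or layers on
#'   the second dimension; layer names taken from `dimnames` if set).
#' @param cfg an [analysis_config()].
#' @return data frame with columns `trial, trace, p1_amp, p1_lat_ms,
#'   n1_amp, n1_lat_ms, kept`.
#' @export
extract_components <- function(epochs, cfg = analysis_config()) {
  stopifnot(isTRUE(epochs$baseline_corrected))
  t_ms <- epochs$t_ms
  w1 <- which(t_ms >= cfg$p1_window_ms[1] & t_ms <= cfg$p1_window_ms[2])
  w2 <- which(t_ms >= cfg$n1_window_ms[1] & t_ms <= cfg$n1_window_ms[2])
  if (!length(w1) || !length(w2))
    stop("component windows fall outside the epoch time axis")
  d <- epochs$data
  n_tr <- dim(d)[1]; n_tc <- dim(d)[2]
  traces <- dimnames(d)[[2]]
  if (is.null(traces)) traces <- as.character(seq_len(n_tc))
  out <- expand.grid(trial = seq_len(n_tr), trace = traces,
                     stringsAsFactors = FALSE)
  p1a <- p1l <- n1a <- n1l <- matrix(0, n_tr, n_tc)
  for (j in seq_len(n_tc)) {
    seg1 <- d[, j, w1, drop = FALSE][, 1, ]
    seg2 <- d[, j, w2, drop = FALSE][, 1, ]
    if (n_tr == 1) { seg1 <- matrix(seg1, 1); seg2 <- matrix(seg2, 1) }
    i1 <- apply(seg1, 1, which.max)   # earliest max (which.max tie-break)
    i2 <- apply(seg2, 1, which.min)
    p1a[, j] <- seg1[cbind(seq_len(n_tr), i1)]
    p1l[, j] <- t_ms[w1][i1]
    n1a[, j] <- seg2[cbind(seq_len(n_tr), i2)]
    n1l[, j] <- t_ms[w2][i2]
  }
  out$p1_amp <- as.vector(p1a); out$p1_lat_ms <- as.vector(p1l)
  out$n1_amp <- as.vector(n1a); out$n1_lat_ms <- as.vector(n1l)
  out$kept <- rep(epochs$keep_mask, times = n_tc)
  out
}
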