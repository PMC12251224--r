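## Stimulation-artifact removal: second-order blind identification
## (SOBI) of temporally structured sources, FFT-based flagging of the
## stimulation components, least-squares sinusoid subtraction, and
## back-projection to the contact level.

#' Orthogonal joint diagonalization of symmetric matrices
#'
#' Jacobi-style sweeps over all index pairs; each rotation angle
#' minimizes the summed squared off-diagonal energy of the stack.
#' Terminates when every rotation angle of a sweep falls below `tol` or
#' after `max_sweeps` sweeps.
#'
#' @param matrices list of symmetric matrices of one common dimension.
#' @param tol rotation-angle convergence tolerance, radians.
#' @param max_sweeps sweep limit.
#' @return orthogonal rotation matrix `V` such that `t(V) %*% M %*% V`
#'   is jointly near-diagonal; attributes `sweeps` and `off_diag_mass`.
#' @export
joint_diagonalize <- function(matrices, tol = 1e-8, max_sweeps = 100) {
  p <- nrow(matrices[[1]])
  if (any(vapply(matrices, function(m) any(dim(m) != p), logical(1))))
    stop("all matrices must share one dimension")
  A <- array(unlist(matrices), c(p, p, length(matrices)))
  V <- diag(p)
  sweeps <- 0
  repeat {
    sweeps <- sweeps + 1
    max_theta <- 0
    for (pp in seq_len(p - 1)) for (qq in (pp + 1):p) {
      u <- A[pp, pp, ] - A[qq, qq, ]
      v <- A[pp, qq, ] + A[qq, pp, ]
      theta <- 0.25 * atan2(2 * sum(u * v), sum(u^2 - v^2))
      if (abs(theta) > max_theta) max_theta <- abs(theta)
      if (abs(theta) < tol) next
      cth <- cos(theta); sth <- sin(theta)
      G <- diag(p); G[pp, pp] <- cth; G[qq, qq] <- cth
      G[pp, qq] <- -sth; G[qq, pp] <- sth
      for (k in seq_len(dim(A)[3]))
        A[, , k] <- crossprod(G, A[, , k]) %*% G
      V <- V %*% G
    }
    if (max_theta < tol || sweeps >= max_sweeps) break
  }
  off <- sum(vapply(seq_len(dim(A)[3]), function(k) {
    M <- A[, , k]; sum(M^2) - sum(diag(M)^2)
  }, numeric(1)))
  attr(V, "sweeps") <- sweeps
  attr(V, "off_diag_mass") <- off
  V
}

## Log-spaced unique lag set (samples) for the covariance stack.
sobi_default_lags <- function(fs, n_lags = 50, max_lag_ms = 500) {
  lags <- unique(round(exp(seq(log(1), log(max_lag_ms / 1000 * fs),
                               length.out = n_lags))))
  lags[lags >= 1]
}

#' SOBI unmixing of a multichannel record
#'
#' Whitens the data (retaining the eigenvector subspace covering
#' `var_keep` of the variance; the stimulation artifact dominates the
#' variance, so essentially nothing is discarded), accumulates
#' symmetrized time-lagged covariance matrices of the whitened data and
#' joint-diagonalizes them. Sources are the rotated whitened channels.
#'
#' @param data numeric matrix `[channels x samples]`.
#' @param lags integer sample lags (default: 50 log-spaced lags up to
#'   500 ms worth of samples at `fs`).
#' @param fs sampling rate (only used for the default lag set).
#' @param var_keep variance fraction retained by the whitener.
#' @return an `unmixing_model`: `mixing` (channels x sources),
#'   `unmixing` (sources x channels), `sources` (sources x samples),
#'   `ac_flags`, `lags`, `rank`, `off_diag_mass`, `center`.
#' @export
sobi_unmix <- function(data, lags = NULL, fs = 1000, var_keep = 0.99999) {
  if (!all(is.finite(data))) stop("non-finite values in input")
  n_ch <- nrow(data); n <- ncol(data)
  if (n_ch < 2) stop("need at least 2 channels")
  if (is.null(lags)) lags <- sobi_default_lags(fs)
  lags <- sort(unique(as.integer(lags)))
  if (n <= max(lags) * 10) stop("record too short for the requested lags")
  ctr <- rowMeans(data)
  X <- data - ctr
  C0 <- tcrossprod(X) / n
  eg <- eigen(C0, symmetric = TRUE)
  pos <- eg$values > max(eg$values) * 1e-12
  if (sum(pos) < n_ch)
    warning("rank-deficient covariance: retaining ", sum(pos), " of ", n_ch,
            " dimensions")
  cum <- cumsum(eg$values[pos]) / sum(eg$values[pos])
  r <- which(cum >= var_keep)[1]
  if (is.na(r)) r <- sum(pos)
  W0 <- diag(1 / sqrt(eg$values[seq_len(r)]), r) %*%
    t(eg$vectors[, seq_len(r), drop = FALSE])
  Z <- W0 %*% X
  Cs <- lapply(lags, function(l) {
    C <- tcrossprod(Z[, seq_len(n - l), drop = FALSE],
                    Z[, (1 + l):n, drop = FALSE]) / (n - l)
    (C + t(C)) / 2
  })
  V <- joint_diagonalize(Cs)
  unmix <- crossprod(V, W0)                      # sources x channels
  mixing <- eg$vectors[, seq_len(r), drop = FALSE] %*%
    diag(sqrt(eg$values[seq_len(r)]), r) %*% V   # channels x sources
  structure(list(mixing = mixing, unmixing = unmix,
                 sources = unmix %*% X, ac_flags = rep(FALSE, r),
                 lags = lags, rank = r,
                 off_diag_mass = attr(V, "off_diag_mass"),
                 center = ctr),
            class = "unmixing_model")
}

#' Flag sources dominated by the stimulation frequency
#'
#' A source is flagged iff its spectral power in `f0 +/- 0.1` Hz exceeds
#' `ratio_threshold` times the local background, the median power over
#' `f0 +/- 0.75` Hz with the `f0 +/- 0.15` Hz core excluded. The local
#' background (rather than a broadband median) keeps 1/f neural noise,
#' which concentrates power at low frequencies, from being mistaken for
#' a narrowband stimulation component. Power in the harmonic bands
#' (2 f0, 3 f0) is reported for diagnostics but does not drive flagging.
#'
#' @param model an `unmixing_model`.
#' @param fs sampling rate of the source time courses, Hz.
#' @param f0 stimulation frequency, Hz.
#' @param ratio_threshold flagging ratio.
#' @return the model with `ac_flags` set and a `flag_report` data frame
#'   (`source, power_ratio, harmonic2_ratio, harmonic3_ratio, flagged`).
#' @export
identify_ac_components <- function(model, fs, f0, ratio_threshold = 10) {
  if (f0 <= 0 || f0 >= fs / 2) stop("f0 must lie in (0, Nyquist)")
  S <- model$sources
  if (ncol(S) < 10 * fs / f0) stop("sources shorter than 10 cycles of f0")
  n <- 2^floor(log2(ncol(S)))   # power-of-two prefix: fast, ample resolution
  freqs <- (seq_len(n) - 1) * fs / n
  half <- freqs <= fs / 2
  band <- function(P, lo, hi) {
    sel <- half & freqs >= lo & freqs <= hi
    if (!any(sel)) return(NA_real_)
    mean(P[sel])
  }
  local_bg <- function(P, fc) {
    sel <- half & freqs >= fc - 0.75 & freqs <= fc + 0.75 &
      abs(freqs - fc) > 0.15
    stats::median(P[sel])
  }
  rep_df <- data.frame(source = seq_len(nrow(S)), power_ratio = NA_real_,
                       harmonic2_ratio = NA_real_, harmonic3_ratio = NA_real_)
  for (i in seq_len(nrow(S))) {
    P <- Mod(stats::fft(S[i, seq_len(n)]))^2
    rep_df$power_ratio[i] <- band(P, f0 - 0.1, f0 + 0.1) / local_bg(P, f0)
    rep_df$harmonic2_ratio[i] <- band(P, 2 * f0 - 0.1, 2 * f0 + 0.1) /
      local_bg(P, 2 * f0)
    rep_df$harmonic3_ratio[i] <- band(P, 3 * f0 - 0.1, 3 * f0 + 0.1) /
      local_bg(P, 3 * f0)
  }
  rep_df$flagged <- rep_df$power_ratio > ratio_threshold
  model$ac_flags <- rep_df$flagged
  model$flag_report <- rep_df
  model
}

#' Subtract the fitted stimulation sinusoid from a time series
#'
#' Least-squares fit of `a*cos(2 pi f0 t) + b*sin(2 pi f0 t)` over the
#' fit region (all samples outside `exclude`, e.g., the stimulation
#' ramps, where the artifact is nonstationary), subtracted everywhere.
#'
#' @param x numeric time series.
#' @param fs sampling rate, Hz.
#' @param f0 frequency to remove, Hz.
#' @param exclude optional list of `c(start_s, end_s)` ranges excluded
#'   from the fit.
#' @return cleaned series with attributes `amplitude` and `phase_deg` of
#'   the removed sinusoid.
#' @export
dft_subtract <- function(x, fs, f0, exclude = NULL) {
  if (f0 <= 0) stop("f0 must be positive")
  n <- length(x)
  keep <- rep(TRUE, n)
  t <- (seq_len(n) - 1) / fs
  for (rg in exclude) keep[t >= rg[1] & t <= rg[2]] <- FALSE
  if (sum(keep) < 2 * fs / f0) stop("fewer than 2 cycles outside excluded ranges")
  fit <- sinusoid_fit(x, fs, f0, idx = which(keep))
  out <- x - (fit$a * cos(2 * pi * f0 * t) + fit$b * sin(2 * pi * f0 * t))
  attr(out, "amplitude") <- fit$amplitude
  attr(out, "phase_deg") <- fit$phase_deg
  out
}

#' Remove the stimulation artifact from a Flash+AC session
#'
#' Composition of [sobi_unmix()] (covariances estimated on an
#' anti-aliased decimated copy, unmixing applied at the full rate),
#' [identify_ac_components()], [dft_subtract()] on every flagged source
#' (fit region excluding the ramps), and back-projection of the removed
#' sinusoids to the contact level. The cleaned record plus the removed
#' reconstruction sum to the input exactly.
#'
#' @param session a `recording_session` with `condition == "FLASH_AC"`.
#' @param cfg an [analysis_config()].
#' @return the cleaned session; attribute `artifact_qc` holds a per-source
#'   report and per-contact attenuation (dB) at the stimulation frequency.
#' @export
remove_ac_artifact <- function(session, cfg = analysis_config()) {
  validate_session(session)
  if (session$condition != "FLASH_AC")
    stop("artifact removal applies to the FLASH_AC condition only")
  X <- session$lfp_signals
  fs <- session$fs_lfp
  f0 <- session$ac_frequency_hz
  dur <- ncol(X) / fs
  ## covariance estimation on a decimated copy (content is band-limited
  ## well below the decimated Nyquist after LFP filtering)
  dec <- max(1, floor(fs / cfg$sobi_fs_cov))
  lags_full <- sobi_default_lags(fs, cfg$sobi_n_lags, cfg$sobi_max_lag_ms)
  model <- sobi_unmix(X[, seq(1, ncol(X), by = dec), drop = FALSE],
                      lags = unique(pmax(1, round(lags_full / dec))))
  ## source time courses at the full rate
  S <- model$unmixing %*% (X - model$center)
  model$sources <- S
  model <- identify_ac_components(model, fs, f0,
                                  ratio_threshold = cfg$ac_ratio_threshold)
  if (!any(model$ac_flags)) {
    warning("no source exceeded the stimulation-power ratio; ",
            "returning the input unchanged")
    attr(session, "artifact_qc") <- model$flag_report
    return(session)
  }
  ramps <- list(c(0, session$ramp_s), c(dur - session$ramp_s, dur))
  flagged <- which(model$ac_flags)
  removed <- matrix(0, length(flagged), ncol(X))
  for (j in seq_along(flagged)) {
    cleaned <- dft_subtract(S[flagged[j], ], fs, f0, exclude = ramps)
    removed[j, ] <- S[flagged[j], ] - cleaned
  }
  X_clean <- X - model$mixing[, flagged, drop = FALSE] %*% removed
  ## QC: attenuation at f0 per contact over the plateau
  plat <- which((seq_len(ncol(X)) - 1) / fs > session$ramp_s &
                (seq_len(ncol(X)) - 1) / fs < dur - session$ramp_s)
  att <- vapply(seq_len(nrow(X)), function(i) {
    p0 <- power_at(X[i, plat], fs, f0)
    p1 <- power_at(X_clean[i, plat], fs, f0)
    10 * log10(p0 / max(p1, .Machine$double.xmin))
  }, numeric(1))
  out <- session
  out$lfp_signals <- X_clean
  attr(out, "artifact_qc") <- list(flag_report = model$flag_report,
                                   attenuation_db = att,
                                   model = model)
  log_stage("remove_ac_artifact",
            sprintf("%d source(s) flagged; median attenuation %.1f dB",
                    length(flagged), stats::median(att)))
  out
}
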