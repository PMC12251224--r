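## RecordingSession: the unit of data every pipeline stage consumes.
## Signals are stored exactly as acquired (gain-multiplied); all analyses
## that need physical units divide by `gain` explicitly.

#' Construct a laminar recording session
#'
#' A `RecordingSession` bundles the continuous multichannel LFP-band
#' signals (contacts x samples, acquisition units, i.e., gain-multiplied),
#' an optional wideband stream for multi-unit analysis, the stimulus onset
#' times, and the acquisition metadata.
#'
#' @param lfp_signals numeric matrix `[n_contacts x n_samples]` in
#'   acquisition units.
#' @param fs_lfp LFP-band sampling rate, Hz.
#' @param stim_onsets_s strictly increasing stimulus onset times, s.
#' @param condition `"FLASH"` (no stimulation) or `"FLASH_AC"`
#'   (concurrent sinusoidal stimulation).
#' @param wideband_signals optional numeric matrix for the wideband
#'   (spike-band) stream.
#' @param fs_wideband wideband sampling rate, Hz (required with
#'   `wideband_signals`; must be at least 4x the upper MUA band edge).
#' @param contact_spacing_mm inter-contact spacing, mm.
#' @param gain acquisition amplifier gain (signals = gain x true volts).
#' @param ac_frequency_hz stimulation frequency, Hz.
#' @param ramp_s stimulation ramp-up/ramp-down duration, s.
#' @return an object of class `recording_session`.
#' @export
recording_session <- function(lfp_signals, fs_lfp, stim_onsets_s, condition,
                              wideband_signals = NULL, fs_wideband = NULL,
                              contact_spacing_mm = 0.1, gain = 10,
                              ac_frequency_hz = 1.5, ramp_s = 30) {
  s <- structure(list(
    lfp_signals = lfp_signals, fs_lfp = fs_lfp,
    wideband_signals = wideband_signals, fs_wideband = fs_wideband,
    contact_spacing_mm = contact_spacing_mm, gain = gain,
    stim_onsets_s = stim_onsets_s, condition = condition,
    ac_frequency_hz = ac_frequency_hz, ramp_s = ramp_s
  ), class = "recording_session")
  validate_session(s)
  s
}

#' Validate a recording session's invariants
#'
#' @param s a `recording_session`.
#' @return `s`, invisibly; signals an error on any violated invariant.
#' @export
validate_session <- function(s) {
  stopifnot(inherits(s, "recording_session"))
  if (!is.matrix(s$lfp_signals) || !is.numeric(s$lfp_signals))
    stop("lfp_signals must be a numeric matrix [contacts x samples]")
  if (nrow(s$lfp_signals) < 3) stop("need at least 3 contacts")
  if (!s$condition %in% c("FLASH", "FLASH_AC"))
    stop("condition must be FLASH or FLASH_AC")
  if (s$gain <= 0) stop("gain must be positive")
  if (s$contact_spacing_mm <= 0) stop("contact_spacing_mm must be positive")
  on <- s$stim_onsets_s
  if (length(on) && any(diff(on) <= 0))
    stop("stim_onsets_s must be strictly increasing")
  dur <- ncol(s$lfp_signals) / s$fs_lfp
  if (length(on) && (min(on) < 0 || max(on) > dur))
    stop("stimulus onset outside the recording")
  if (!is.null(s$wideband_signals)) {
    if (is.null(s$fs_wideband)) stop("fs_wideband required with wideband")
    if (s$fs_wideband < 4 * 5000)
      stop("fs_wideband must be >= 4x the upper MUA band edge (5 kHz)")
    if (nrow(s$wideband_signals) != nrow(s$lfp_signals))
      stop("wideband and LFP contact counts differ")
  }
  invisible(s)
}

#' @export
print.recording_session <- function(x, ...) {
  cat(sprintf(
    "<recording_session> %s: %d contacts x %d samples @ %g Hz, %d onsets%s\n",
    x$condition, nrow(x$lfp_signals), ncol(x$lfp_signals), x$fs_lfp,
    length(x$stim_onsets_s),
    if (is.null(x$wideband_signals)) "" else
      sprintf(", wideband @ %g Hz", x$fs_wideband)))
  invisible(x)
}

## On-disk container: a directory holding meta.json plus Feather files.
## Feather keeps the float64 samples bit-exact and is readable from any
## Arrow binding, so the container stays language-agnostic and
## partial-read friendly (each array is its own file).

.write_matrix_feather <- function(m, path) {
  df <- as.data.frame(t(m))
  names(df) <- sprintf("c%02d", seq_len(nrow(m)))
  arrow::write_feather(df, path)
}

.read_matrix_feather <- function(path) {
  df <- arrow::read_feather(path)
  m <- t(as.matrix(as.data.frame(df)))
  dimnames(m) <- NULL
  m
}

#' Write a session to its on-disk container
#'
#' The container is a directory with `meta.json` (scalar metadata),
#' `lfp.feather`, `onsets.feather` and, when present, `wideband.feather`.
#' All numeric arrays round-trip bit-exactly.
#'
#' @param session a validated `recording_session`.
#' @param path directory to create.
#' @param overwrite overwrite an existing container? Default `FALSE`.
#' @return `path`, invisibly.
#' @export
write_session <- function(session, path, overwrite = FALSE) {
  validate_session(session)
  if (dir.exists(path) || file.exists(path)) {
    if (!overwrite) stop("path exists; use overwrite = TRUE: ", path)
    unlink(path, recursive = TRUE)
  }
  ok <- dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!ok) stop("cannot create container directory: ", path)
  meta <- list(
    format = "lamtacs-session-v1",
    fs_lfp = session$fs_lfp,
    fs_wideband = session$fs_wideband,
    contact_spacing_mm = session$contact_spacing_mm,
    gain = session$gain,
    condition = session$condition,
    ac_frequency_hz = session$ac_frequency_hz,
    ramp_s = session$ramp_s,
    n_contacts = nrow(session$lfp_signals),
    has_wideband = !is.null(session$wideband_signals)
  )
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  .write_matrix_feather(session$lfp_signals, file.path(path, "lfp.feather"))
  arrow::write_feather(data.frame(onset_s = session$stim_onsets_s),
                       file.path(path, "onsets.feather"))
  if (!is.null(session$wideband_signals))
    .write_matrix_feather(session$wideband_signals,
                          file.path(path, "wideband.feather"))
  invisible(path)
}

#' Read a session from its on-disk container
#'
#' @param path container directory written by [write_session()].
#' @return a validated `recording_session`.
#' @export
read_session <- function(path) {
  if (!dir.exists(path)) stop("no session container at: ", path)
  meta_path <- file.path(path, "meta.json")
  if (!file.exists(meta_path)) stop("container missing meta.json: ", path)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  req <- c("fs_lfp", "gain", "condition", "contact_spacing_mm",
           "ac_frequency_hz", "ramp_s")
  miss <- setdiff(req, names(meta))
  if (length(miss)) stop("container missing metadata field(s): ",
                         paste(miss, collapse = ", "))
  lfp_path <- file.path(path, "lfp.feather")
  if (!file.exists(lfp_path)) stop("container missing dataset: lfp")
  on_path <- file.path(path, "onsets.feather")
  if (!file.exists(on_path)) stop("container missing dataset: stim_onsets")
  lfp <- .read_matrix_feather(lfp_path)
  onsets <- as.numeric(arrow::read_feather(on_path)$onset_s)
  wb <- NULL
  wb_path <- file.path(path, "wideband.feather")
  if (isTRUE(meta$has_wideband)) {
    if (!file.exists(wb_path)) stop("container missing dataset: wideband")
    wb <- .read_matrix_feather(wb_path)
  }
  recording_session(
    lfp_signals = lfp, fs_lfp = as.numeric(meta$fs_lfp),
    stim_onsets_s = onsets,
    condition = meta$condition, wideband_signals = wb,
    fs_wideband = if (is.null(meta$fs_wideband) ||
                      is.na(meta$fs_wideband[1])) NULL else
                        as.numeric(meta$fs_wideband),
    contact_spacing_mm = as.numeric(meta$contact_spacing_mm),
    gain = as.numeric(meta$gain),
    ac_frequency_hz = as.numeric(meta$ac_frequency_hz),
    ramp_s = as.numeric(meta$ramp_s))
}

#' Default analysis configuration
#'
#' All stage parameters of the pipeline with their default settings:
#' LFP band 0.5-100 Hz (4th-order Butterworth, zero phase) with a 60 Hz
#' notch and 1 kHz target rate; -50..250 ms epochs with -50..0 ms
#' baseline; +/-5 SD trial rejection; P1 search 55-90 ms, N1 100-140 ms;
#' AC narrowband 0.5-2 Hz; 20 x 18 deg phase bins with 5000-shuffle
#' permutation; cluster permutation with 2000 iterations at critical
#' value 0.01 (cluster-forming pointwise alpha 0.05); MUA band
#' 300-5000 Hz, threshold factor 3.5, 10 ms PSTH bins, +/-45 deg
#' peak/trough windows.
#'
#' @param ... overrides for any named default.
#' @return a named list of parameters (class `analysis_config`).
#' @export
analysis_config <- function(...) {
  cfg <- list(
    lfp_band_hz = c(0.5, 100), lfp_filter_order = 4,
    notch_hz = 60, notch_q = 35, fs_target = 1000,
    epoch_window_ms = c(-50, 250), baseline_ms = c(-50, 0),
    reject_sd = 5, reject_pool = "per_contact",
    p1_window_ms = c(55, 90), n1_window_ms = c(100, 140),
    ac_band_hz = c(0.5, 2), ac_f0_hz = 1.5,
    sobi_n_lags = 50, sobi_max_lag_ms = 500, sobi_fs_cov = 500,
    ac_ratio_threshold = 10,
    n_phase_bins = 20, n_perm_phase = 5000, phase_mode = "unimodal",
    n_perm_cluster = 2000, cluster_alpha = 0.01, cluster_forming_alpha = 0.05,
    cluster_adjacency = "spatiotemporal",
    mua_band_hz = c(300, 5000), mua_alpha = 3.5, mua_dead_time_ms = 1,
    psth_bin_ms = 10, psth_window_ms = c(0, 250), phase_lock_window_deg = 45,
    field_rise_k = 2,
    seed = 1L
  )
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config field(s): ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  class(cfg) <- "analysis_config"
  cfg
}

#' Export pipeline results as CSV files
#'
#' Writes one CSV per result family present in `bundle`: `components.csv`
#' (per-trial P1/N1 table), `phase_results.csv` (circular statistics),
#' `clusters.csv`, `psth.csv`, `rate_tests.csv`, `field_profile.csv`,
#' `layers.csv`. Files are UTF-8 with a header row and '.' decimal;
#' identical inputs produce byte-identical files.
#'
#' @param bundle named list of stage outputs (data frames, or objects with
#'   an `as.data.frame`-able table); at least one must be present.
#' @param dir output directory (created if missing).
#' @return character vector of the files written, invisibly.
#' @export
export_results <- function(bundle, dir) {
  known <- c("components", "phase_results", "clusters", "psth",
             "rate_tests", "field_profile", "layers")
  present <- intersect(names(bundle), known)
  present <- present[!vapply(bundle[present], is.null, logical(1))]
  if (!length(present)) stop("empty result bundle: nothing to export")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  for (nm in present) {
    df <- as.data.frame(bundle[[nm]])
    f <- file.path(dir, paste0(nm, ".csv"))
    utils::write.csv(df, f, row.names = FALSE, fileEncoding = "UTF-8")
    written <- c(written, f)
  }
  invisible(written)
}
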