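## End-to-end orchestration: preprocess both conditions, clean the
## stimulated record, label stimulation phases, assign layers, extract
## components, run the phase-dependency statistics with the virtual-AC
## negative control, the cluster comparison, and (when a wideband
## stream is present) the multi-unit analyses.

#' Run the full laminar stimulation analysis
#'
#' Stage order: LFP filtering of both conditions; artifact removal on
#' the stimulated condition; phase labels from the raw (pre-cleaning)
#' stimulated record's narrowband waveform (cleaning removes the very
#' signal that defines phase); epoching + baseline + trial rejection;
#' field profile and CSD-based layer assignment; layer averaging and
#' P1/N1 extraction; phase-binned circular statistics with permutation
#' nulls per layer and component, plus the virtual-AC control on the
#' no-stimulation condition; cluster-based permutation comparison of
#' conditions; multi-unit PSTH and firing-rate comparisons when a
#' wideband stream exists (skipped with a note otherwise).
#'
#' @param flash `recording_session`, condition `FLASH`.
#' @param flash_ac `recording_session`, condition `FLASH_AC`.
#' @param cfg an [analysis_config()]; `cfg$seed` governs every
#'   permutation.
#' @return a `run_report` list: `config`, `layers`, `field`,
#'   `components`, `phase_results`, `clusters`, `psth`, `rate_tests`,
#'   `qc` (artifact attenuation, trials kept, Rayleigh p of the phase
#'   labels), plus intermediate objects for inspection.
#' @export
run_all <- function(flash, flash_ac, cfg = analysis_config()) {
  validate_session(flash); validate_session(flash_ac)
  if (flash$condition != "FLASH" || flash_ac$condition != "FLASH_AC")
    stop("condition labels are swapped or invalid")
  log_stage("run_all", sprintf("seed %d", cfg$seed))

  ## 1. LFP conditioning
  f_flash <- filter_lfp(flash, cfg)
  f_ac_raw <- filter_lfp(flash_ac, cfg)

  ## 2. artifact removal (phase labels are taken before cleaning)
  ac_nb <- extract_ac_waveform(f_ac_raw, cfg)
  f_ac <- remove_ac_artifact(f_ac_raw, cfg)
  qc_art <- attr(f_ac, "artifact_qc")

  ## 3. phase labels from the strongest-artifact contact
  ref_contact <- which.max(apply(ac_nb, 1, stats::sd))
  labels_ac <- phase_at_onsets(ac_nb[ref_contact, ], flash_ac$stim_onsets_s,
                               cfg)
  labels_virtual <- virtual_ac_labels(flash, cfg$ac_f0_hz)
  ray <- rayleigh_test(labels_ac[labels_ac$valid, ])

  ## 4. epochs
  ep_flash <- reject_trials(epoch_and_baseline(f_flash, cfg), cfg)
  ep_ac <- reject_trials(epoch_and_baseline(f_ac, cfg), cfg)

  ## 5. layers from the Flash evoked average + the field profile
  ev_flash <- apply(ep_flash$data[ep_flash$keep_mask, , , drop = FALSE],
                    c(2, 3), mean)
  csd <- compute_csd(ev_flash, flash$contact_spacing_mm)
  field <- field_profile(ac_nb, flash_ac, cfg)
  layers <- assign_layers(csd, field, t_ms = ep_flash$t_ms)

  ## 6. layer averages and components
  lay_flash <- layer_average(ep_flash, layers)
  lay_ac <- layer_average(ep_ac, layers)
  comp_flash <- extract_components(lay_flash, cfg)
  comp_ac <- extract_components(lay_ac, cfg)
  comp_flash$condition <- "FLASH"; comp_ac$condition <- "FLASH_AC"

  ## 7. phase dependency per layer x component (+ virtual control)
  phase_tab <- NULL
  phase_seed_stream <- 10L
  run_phase <- function(comp, labels, condition, lay_names, trial_index) {
    out <- NULL
    for (lay in lay_names) for (cc in c("P1", "N1")) {
      sub <- comp[comp$trace == lay & comp$kept, ]
      amp <- if (cc == "P1") sub$p1_amp else abs(sub$n1_amp)
      ph <- labels$phase_deg[match(trial_index[sub$trial], labels$trial)]
      ok <- is.finite(ph) & is.finite(amp)
      if (sum(ok) < 20) next
      phase_seed_stream <<- phase_seed_stream + 1L
      res <- permutation_test_phase(amp[ok], ph[ok], mode = cfg$phase_mode,
                                    n_perm = cfg$n_perm_phase,
                                    seed = derive_seed(cfg$seed,
                                                       phase_seed_stream))
      out <- rbind(out, data.frame(
        condition = condition, layer = lay, component = cc,
        mode = res$mode, direction_deg = res$mean_direction_deg,
        R = res$R, z = res$z_score, p = res$p_value,
        n_perm = res$n_perm, significant = res$significant,
        n_trials = res$n_trials))
    }
    out
  }
  lay_names <- lay_ac$layer_labels
  phase_tab <- rbind(
    run_phase(comp_ac, labels_ac, "FLASH_AC", lay_names,
              ep_ac$trial_index),
    run_phase(comp_flash, labels_virtual, "FLASH_VIRTUAL", lay_names,
              ep_flash$trial_index))

  ## 8. cluster comparison across contacts
  clus <- cluster_permutation_test(
    ep_flash, ep_ac, n_perm = cfg$n_perm_cluster, alpha = cfg$cluster_alpha,
    forming_alpha = cfg$cluster_forming_alpha,
    adjacency = cfg$cluster_adjacency, seed = derive_seed(cfg$seed, 2L))

  ## 9. multi-unit analyses
  psth <- NULL; rate_tests <- NULL; mua_note <- NULL
  if (!is.null(flash$wideband_signals) &&
      !is.null(flash_ac$wideband_signals)) {
    sp_flash <- detect_spikes(filter_mua(flash, cfg), flash$fs_wideband,
                              cfg$mua_alpha, cfg$mua_dead_time_ms)
    sp_ac <- detect_spikes(filter_mua(flash_ac, cfg), flash_ac$fs_wideband,
                           cfg$mua_alpha, cfg$mua_dead_time_ms)
    ps_flash <- compute_psth(sp_flash, flash$stim_onsets_s, layers,
                             cfg$psth_bin_ms, cfg$psth_window_ms)
    ps_ac <- compute_psth(sp_ac, flash_ac$stim_onsets_s, layers,
                          cfg$psth_bin_ms, cfg$psth_window_ms)
    psth <- rbind(
      data.frame(condition = "FLASH", layer = rownames(ps_flash$rates),
                 ps_flash$rates, check.names = FALSE),
      data.frame(condition = "FLASH_AC", layer = rownames(ps_ac$rates),
                 ps_ac$rates, check.names = FALSE))
    rate_of <- function(ps, lay) ps$trial_rates$rate[ps$trial_rates$layer == lay]
    tests <- list()
    for (lay in intersect(c("L23", "L56"), rownames(ps_flash$rates))) {
      r <- compare_firing(rate_of(ps_ac, lay), rate_of(ps_flash, lay),
                          "unpaired")
      tests[[length(tests) + 1]] <- data.frame(
        comparison = paste0(lay, ": FLASH_AC vs FLASH"),
        design = "unpaired", t = r$t, p = r$p_value)
    }
    if (all(c("L23", "L56") %in% rownames(ps_flash$rates))) {
      for (cond in c("FLASH", "FLASH_AC")) {
        ps <- if (cond == "FLASH") ps_flash else ps_ac
        r <- compare_firing(rate_of(ps, "L56"), rate_of(ps, "L23"), "paired")
        tests[[length(tests) + 1]] <- data.frame(
          comparison = paste0(cond, ": L56 vs L23"),
          design = "paired", t = r$t, p = r$p_value)
      }
    }
    ## peak/trough selection on the stimulated condition
    pk <- select_phase_locked_trials(labels_ac, "peak",
                                     cfg$phase_lock_window_deg)
    tr <- select_phase_locked_trials(labels_ac, "trough",
                                     cfg$phase_lock_window_deg)
    for (lay in intersect(c("L23", "L56"), rownames(ps_ac$rates))) {
      ra <- rate_of(ps_ac, lay)
      if (length(pk) >= 2 && length(tr) >= 2) {
        r <- compare_firing(ra[pk], ra[tr], "unpaired")
        tests[[length(tests) + 1]] <- data.frame(
          comparison = paste0(lay, ": peak vs trough"),
          design = "unpaired", t = r$t, p = r$p_value)
      }
    }
    rate_tests <- do.call(rbind, tests)
  } else {
    mua_note <- "MUA analyses skipped: no wideband stream"
    log_stage("run_all", mua_note)
  }

  structure(list(
    config = cfg,
    layers = layers, field = field, csd = csd,
    components = rbind(comp_flash, comp_ac),
    phase_results = phase_tab,
    clusters = clus$table, cluster_result = clus,
    psth = psth, rate_tests = rate_tests, mua_note = mua_note,
    phase_labels = labels_ac, virtual_labels = labels_virtual,
    epochs_flash = ep_flash, epochs_flash_ac = ep_ac,
    evoked_flash = ev_flash,
    qc = list(
      attenuation_db = if (is.list(qc_art)) qc_art$attenuation_db else NULL,
      trials_kept_flash = sum(ep_flash$keep_mask),
      trials_kept_flash_ac = sum(ep_ac$keep_mask),
      rayleigh_p = ray$p_value)
  ), class = "run_report")
}
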