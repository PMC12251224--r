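#!/usr/bin/env Rscript
## Run the full analysis on the simulated pair: filtering, artifact
## removal, phase labels, layer assignment, P1/N1 components, circular
## phase statistics with the virtual-AC control, and the cluster-based
## condition comparison. Writes every result family as CSV.

suppressMessages(library(lamtacs))

sess_dir <- "results/sessions"
if (!dir.exists(file.path(sess_dir, "flash")))
  stop("run analysis/01_simulate.R first")

flash <- read_session(file.path(sess_dir, "flash"))
flash_ac <- read_session(file.path(sess_dir, "flash_ac"))
truth <- readRDS(file.path(sess_dir, "ground_truth.rds"))

report <- run_all(flash, flash_ac, analysis_config(seed = 7))

export_results(list(components = report$components,
                    phase_results = report$phase_results,
                    clusters = report$clusters,
                    layers = report$layers,
                    field_profile = report$field),
               "results/tables")

## what the run found, against the generator truth
cat("\n-- artifact removal: attenuation at 1.5 Hz (dB):",
    sprintf("%.0f-%.0f", min(report$qc$attenuation_db),
            max(report$qc$attenuation_db)), "\n")
cat("-- layer assignment errors (contacts):",
    sum(report$layers$label != truth$layer_labels), "of 23 mislabeled\n")
ph <- report$phase_results
deep <- ph$condition == "FLASH_AC" & ph$layer %in% c("L4AB", "L4C", "L56")
cat("-- deep-layer phase preference significant:",
    sum(ph$significant[deep]), "of", sum(deep), "tests\n")
cat("-- superficial + virtual-control significant:",
    sum(ph$significant[!deep]), "of", sum(!deep), "tests (expect 0)\n")
cat("-- recovered P1 preferred phase (deep):",
    sprintf("%.0f deg (injected %.0f deg)\n",
            mean(ph$direction_deg[deep & ph$component == "P1"]),
            truth$config$mod_phi_pref_deg))
cat("Tables written under results/tables\n")
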