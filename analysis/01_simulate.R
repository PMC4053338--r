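#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study.
#
# Simulates a full camera-trap scavenging study under the package's default
# generating truth: 6 transects x 5 carcasses at 0.05-4 km from the
# farm-forest boundary, half deployed in winter and half in spring,
# monitored for 100 days.  Writes the three study tables plus a truth
# sidecar so later stages can measure parameter recovery.

suppressPackageStartupMessages(library(carrion))

seed <- 20260901
dir.create("results/study", recursive = TRUE, showWarnings = FALSE)

study <- simulate_study(default_sim_truth(seed), n_transects = 6,
                        horizon_days = 100, seed = seed)

write_sites(study$sites, "results/study/sites.csv")
write_events(study$events, "results/study/events.csv")
write_inspections(study$inspections, "results/study/inspections.csv")
jsonlite::write_json(study$truth, "results/study/truth.json",
                     auto_unbox = TRUE, digits = NA, force = TRUE)

use <- carcass_use_summary(study$events, study$sites)
cat("Simulated study:", nrow(study$sites), "carcasses,",
    nrow(study$events), "events,", nrow(study$inspections),
    "inspections\n")
cat("Carcasses visited:", paste(use$species, use$n_visited,
                                collapse = ", "), "\n")
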