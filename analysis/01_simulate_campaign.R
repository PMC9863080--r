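#!/usr/bin/env Rscript
# Step 1 of the workflow: generate a synthetic multi-laboratory bottle-
# bioassay campaign with known ground-truth curves.
#
# The design mirrors the standard two-step protocol's Step 2: six serial
# concentrations, each bioassay exposing 4 replicate bottles of 25 mosquitoes
# per concentration plus 2 control bottles of 25, run in triplicate per
# laboratory (~300 mosquitoes/concentration). Three laboratories share a base
# curve (true LC50 = 1 ug/bottle, 3% background mortality) perturbed on the
# (log B, C) scale to emulate between-laboratory heterogeneity. A fourth
# series emulates an oviposition-inhibition campaign for a sterilizing
# compound.
#
# Outputs (results/):
#   campaign_mortality.csv  canonical bioassay CSV, 3 labs x 3 bioassays
#   campaign_oviposition.csv  single-lab oviposition campaign
#   ground_truth.json       per-laboratory true parameters and LC/OI values

library(bottlebioassay)

seed <- 20260922L
out_dir <- "results"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

base <- curve_params(B = 3, C = 0, E = 1, Z = 0.03)
labs <- c("LAB_A", "LAB_B", "LAB_C")
curves <- perturb_curves(base, labs, scale = 0.15, seed = seed)

design <- campaign_design()
campaign <- simulate_campaign(curves, design, seed = seed,
                              species = "An. stephensi",
                              insecticide = "clothianidin-like")
write_bioassay_csv(campaign, file.path(out_dir, "campaign_mortality.csv"))

ovi <- simulate_oviposition(curve_params(B = 2.5, C = log(8), E = 1, Z = 0),
                            control_laying_rate = 0.75, design, seed = seed + 1L,
                            institution = "LAB_A", species = "An. gambiae",
                            insecticide = "pyriproxyfen-like")
write_bioassay_csv(ovi, file.path(out_dir, "campaign_oviposition.csv"))

truth <- list(
  seed = seed,
  design = unclass(design),
  laboratories = lapply(curves, function(cp)
    list(B = cp$B, C = cp$C, E = cp$E, Z = cp$Z,
         lc50 = invert_lc(cp, 0.5), lc99 = invert_lc(cp, 0.99))),
  oviposition = list(B = 2.5, C = log(8), E = 1,
                     control_laying_rate = 0.75,
                     oi50 = invert_lc(curve_params(2.5, log(8)), 0.5))
)
jsonlite::write_json(truth, file.path(out_dir, "ground_truth.json"),
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)

cat("Simulated", nrow(campaign$records), "mortality records across",
    length(labs), "laboratories and", nrow(ovi$records),
    "oviposition records.\n")
cat("True LC50 by laboratory:",
    paste(sprintf("%s = %.3f", labs,
                  vapply(curves, invert_lc, numeric(1), q = 0.5)),
          collapse = ", "), "ug/bottle\n")
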