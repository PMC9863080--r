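#!/usr/bin/env Rscript
# Step 4: within-bioassay variability.
#
# For every pooled fit from step 2, scores each observed data point against
# the fitted line draw by draw (mean absolute deviation per iteration, in
# percentage points), summarizes iterations by their median with a central
# 95% interval, and aggregates institutions to species level (mean, with a
# min-max interval once several institutions contribute).
#
# Outputs (results/): variability_institution.csv, variability_species.csv

library(bottlebioassay)

out_dir <- "results"
fit_dir <- file.path(out_dir, "fits")

inputs <- c(mortality = "campaign_mortality.csv",
            oviposition = "campaign_oviposition.csv")
rows <- list()
for (jf in list.files(fit_dir, pattern = "_pooled\\.json$", full.names = TRUE)) {
  meta <- jsonlite::read_json(jf)
  scope <- unlist(meta$scope)
  pooled <- as_posterior_draws(
    read_draws_csv(sub("\\.json$", "_draws.csv", jf)), scope = scope)
  ep <- if (grepl("pyriproxyfen", basename(jf))) "OI" else "mortality"
  src <- if (ep == "OI") inputs[["oviposition"]] else inputs[["mortality"]]
  ds <- read_bioassay_csv(file.path(out_dir, src))
  rec <- ds$records[ds$records$institution == scope[["institution"]] &
                      ds$records$species == scope[["species"]] &
                      ds$records$insecticide == scope[["insecticide"]], ]
  n <- ifelse(rec$endpoint_type == "oviposition", rec$n_chambered, rec$n_exposed)
  dat <- data.frame(x = rec$concentration_ug_per_bottle, n = n,
                    y = rec$n_responded)
  rows[[basename(jf)]] <- within_bioassay_variability(pooled, dat,
                                                      endpoint_type = ep)
}
variability <- do.call(rbind, rows)
rownames(variability) <- NULL
utils::write.csv(variability, file.path(out_dir, "variability_institution.csv"),
                 row.names = FALSE)

key <- interaction(variability$species, variability$insecticide, drop = TRUE)
species <- do.call(rbind, lapply(split(variability, key), aggregate_variability))
rownames(species) <- NULL
utils::write.csv(species, file.path(out_dir, "variability_species.csv"),
                 row.names = FALSE)

cat("Within-bioassay variability (percentage points):\n")
print(variability, digits = 3)
cat("\nSpecies-level aggregation:\n")
print(species, digits = 3)
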