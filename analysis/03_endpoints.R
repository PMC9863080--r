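#!/usr/bin/env Rscript
# Step 3: invert the fitted curves into susceptibility endpoints.
#
# Reads the serialized draws from step 2, computes LC50/LC99 (or OI50/OI99)
# posterior medians with min-max ranges over the per-bioassay fits, averages
# institutions into species-level summaries, and derives discriminating
# concentrations as twice the LC99 basis. Where ground truth is available
# (synthetic campaign) the recovery error is printed.
#
# Outputs (results/):
#   endpoints_institution.csv, endpoints_species.csv, discriminating_concentrations.csv

library(bottlebioassay)

out_dir <- "results"
fit_dir <- file.path(out_dir, "fits")
quantiles <- c(0.5, 0.99)

pooled_files <- list.files(fit_dir, pattern = "_pooled\\.json$", full.names = TRUE)
stopifnot(length(pooled_files) >= 1L)

institution <- list()
for (jf in pooled_files) {
  meta <- jsonlite::read_json(jf)
  tag <- sub("_pooled\\.json$", "", basename(jf))
  pooled <- as_posterior_draws(
    read_draws_csv(sub("\\.json$", "_draws.csv", jf)),
    scope = unlist(meta$scope), converged = isTRUE(meta$converged))
  rep_files <- list.files(fit_dir, pattern = paste0("^", tag, "_rep\\d+_draws\\.csv$"),
                          full.names = TRUE)
  reps <- lapply(rep_files, function(f)
    as_posterior_draws(read_draws_csv(f), scope = unlist(meta$scope)))
  ep_type <- if (grepl("pyriproxyfen", tag)) "OI" else "LC"
  institution[[tag]] <- do.call(rbind, lapply(quantiles, function(q)
    institution_estimate(pooled, reps, q, endpoint_type = ep_type)))
}
institution <- do.call(rbind, institution)
rownames(institution) <- NULL
utils::write.csv(institution, file.path(out_dir, "endpoints_institution.csv"),
                 row.names = FALSE)

key <- interaction(institution$species, institution$insecticide, institution$q,
                   drop = TRUE)
species <- do.call(rbind, lapply(split(institution, key), species_summary))
rownames(species) <- NULL
utils::write.csv(species, file.path(out_dir, "endpoints_species.csv"),
                 row.names = FALSE)

basis <- species[species$q == 0.99 & species$endpoint_type == "LC", , drop = FALSE]
if (nrow(basis)) {
  dc <- data.frame(species = basis$species, insecticide = basis$insecticide,
                   lc99 = basis$value,
                   dc = vapply(seq_len(nrow(basis)), function(i)
                     compute_dc(basis[i, ]), numeric(1)))
  utils::write.csv(dc, file.path(out_dir, "discriminating_concentrations.csv"),
                   row.names = FALSE)
}

cat("Institution-level endpoints:\n")
print(institution[, c("institution", "species", "insecticide", "endpoint_type",
                      "q", "value", "range_low", "range_high")], digits = 3)
cat("\nSpecies-level summaries (mean of institutions):\n")
print(species, digits = 3)

truth_path <- file.path(out_dir, "ground_truth.json")
if (file.exists(truth_path)) {
  truth <- jsonlite::read_json(truth_path)
  true_lc50 <- mean(vapply(truth$laboratories, function(l) l$lc50, numeric(1)))
  est <- species$value[species$q == 0.5 & species$endpoint_type == "LC"]
  cat(sprintf("\nMean true LC50 %.3f vs species-level estimate %.3f (%.1f%% error)\n",
              true_lc50, est[1], 100 * abs(est[1] - true_lc50) / true_lc50))
}
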