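#!/usr/bin/env Rscript
# Step 5: concentration-response figures.
#
# Redraws the fitted curves: posterior-median line per institution, ribbon
# spanning the per-bioassay median curves, observed pooled proportions sized
# by the number tested, log-scaled concentration axis, one panel per
# species-insecticide combination. Curves span only the observed
# concentration range.
#
# Output (results/figures/): dose_response_mortality.pdf

library(bottlebioassay)

out_dir <- "results"
fit_dir <- file.path(out_dir, "fits")
fig_dir <- file.path(out_dir, "figures")
dir.create(fig_dir, showWarnings = FALSE, recursive = TRUE)

ds <- read_bioassay_csv(file.path(out_dir, "campaign_mortality.csv"))
fits <- list(); replicate_fits <- list()
for (jf in list.files(fit_dir, pattern = "_pooled\\.json$", full.names = TRUE)) {
  if (grepl("pyriproxyfen", basename(jf))) next
  meta <- jsonlite::read_json(jf)
  tag <- sub("_pooled\\.json$", "", basename(jf))
  scope <- unlist(meta$scope)
  fits[[tag]] <- as_posterior_draws(
    read_draws_csv(sub("\\.json$", "_draws.csv", jf)), scope = scope)
  rep_files <- list.files(fit_dir,
                          pattern = paste0("^", tag, "_rep\\d+_draws\\.csv$"),
                          full.names = TRUE)
  replicate_fits[[tag]] <- lapply(rep_files, function(f)
    as_posterior_draws(read_draws_csv(f), scope = scope))
}

gg <- plot_dose_response(fits, replicate_fits, ds)
ggplot2::ggsave(file.path(fig_dir, "dose_response_mortality.pdf"), gg,
                width = 9, height = 5)
cat("Wrote", file.path(fig_dir, "dose_response_mortality.pdf"), "\n")
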