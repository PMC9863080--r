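#' Run the full concentration-response analysis over a campaign
#'
#' The complete analysis chain for a multi-laboratory bioassay campaign:
#' quality control (\code{\link{apply_qc}}), one pooled Bayesian fit per
#' (institution, species, insecticide) scope over all of that scope's
#' accepted bioassays, one fit per individual bioassay for the min-max
#' uncertainty ranges, endpoint inversion at the requested quantiles,
#' within-bioassay variability, aggregation to species level, and
#' discriminating-concentration derivation.
#'
#' @param ds a \code{\link{bioassay_dataset}}.
#' @param quantiles corrected response quantiles to report (default LC50 and
#'   LC99).
#' @param priors a \code{\link{prior_spec}}.
#' @param config an \code{\link{mcmc_config}}; every scope and bioassay fit
#'   receives a deterministic sub-seed of \code{config$seed}.
#' @param dc_basis LC quantile on which discriminating concentrations are
#'   based (default 0.99); must be among \code{quantiles} for DCs to be
#'   reported.
#' @param dc_multiplier multiple of the basis LC (default 2).
#' @param point_summary across-point aggregation for the variability
#'   statistic (\code{"mean"} or \code{"median"}).
#' @return list with elements \code{qc_report}, \code{fits} (named list of
#'   pooled \code{posterior_draws}), \code{replicate_fits}, \code{endpoints}
#'   (institution level), \code{species_endpoints}, \code{variability},
#'   \code{species_variability}, \code{dc} (species-level discriminating
#'   concentrations).
#' @export
analyze_campaign <- function(ds, quantiles = c(0.5, 0.99),
                             priors = prior_spec(), config = mcmc_config(),
                             dc_basis = 0.99, dc_multiplier = 2,
                             point_summary = "mean") {
  stopifnot(inherits(ds, "bioassay_dataset"), all(quantiles > 0),
            all(quantiles < 1))
  qc <- apply_qc(ds)
  rec <- qc$accepted$records
  if (nrow(rec) == 0L) stop("no bioassays accepted by QC", call. = FALSE)
  scope_key <- interaction(rec$institution, rec$species, rec$insecticide,
                           drop = TRUE, sep = "\r")
  groups <- split(seq_len(nrow(rec)), scope_key)
  seeds <- derive_seeds(config$seed, length(groups))
  fits <- list(); replicate_fits <- list()
  endpoints <- list(); variability <- list()
  for (k in seq_along(groups)) {
    g <- rec[groups[[k]], , drop = FALSE]
    scope <- c(institution = g$institution[1L], species = g$species[1L],
               insecticide = g$insecticide[1L])
    scope_id <- paste(scope, collapse = "|")
    cfg <- config; cfg$seed <- seeds[k]
    gds <- bioassay_dataset(g, provenance = qc$accepted$provenance)
    pooled <- fit_dose_response(gds, priors = priors, config = cfg,
                                scope = scope)
    cfg_rep <- config; cfg_rep$seed <- seeds[k] + 1L
    reps <- fit_per_replicate(gds, priors = priors, config = cfg_rep)
    fits[[scope_id]] <- pooled
    replicate_fits[[scope_id]] <- reps
    ep_type <- if (g$endpoint_type[1L] == "oviposition") "OI" else "LC"
    endpoints[[scope_id]] <- do.call(rbind, lapply(quantiles, function(q)
      institution_estimate(pooled, reps, q, endpoint_type = ep_type)))
    variability[[scope_id]] <- within_bioassay_variability(
      pooled, fit_data(gds), point_summary = point_summary,
      endpoint_type = if (ep_type == "OI") "OI" else "mortality")
  }
  endpoints <- do.call(rbind, endpoints)
  variability <- do.call(rbind, variability)
  rownames(endpoints) <- rownames(variability) <- NULL
  sp_key <- interaction(endpoints$species, endpoints$insecticide, endpoints$q,
                        drop = TRUE)
  species_endpoints <- do.call(rbind, lapply(split(endpoints, sp_key),
                                             species_summary))
  va_key <- interaction(variability$species, variability$insecticide,
                        drop = TRUE)
  species_variability <- do.call(rbind, lapply(split(variability, va_key),
                                               aggregate_variability))
  rownames(species_endpoints) <- rownames(species_variability) <- NULL
  dc <- NULL
  basis <- species_endpoints[species_endpoints$q == dc_basis &
                               species_endpoints$endpoint_type == "LC", ,
                             drop = FALSE]
  if (nrow(basis)) {
    dc <- basis[, c("species", "insecticide", "q", "value")]
    names(dc)[names(dc) == "value"] <- "lc_basis_value"
    dc$dc <- vapply(seq_len(nrow(basis)), function(i)
      compute_dc(basis[i, ], multiplier = dc_multiplier), numeric(1))
    rownames(dc) <- NULL
  }
  list(qc_report = qc$report, fits = fits, replicate_fits = replicate_fits,
       endpoints = endpoints, species_endpoints = species_endpoints,
       variability = variability, species_variability = species_variability,
       dc = dc)
}

#' Serialise a fit to JSON (summaries) and CSV (draws)
#'
#' Writes parameter summaries, convergence diagnostics and scope labels as
#' JSON, and the retained draws as a columnar CSV with \code{chain} and
#' \code{iteration} columns that \code{\link{read_draws_csv}} restores
#' losslessly.
#'
#' @param fit a \code{posterior_draws} object.
#' @param json_path,draws_path output paths; either may be \code{NULL} to
#'   skip that artefact.
#' @return invisibly, the list serialised to JSON.
#' @export
write_fit_json <- function(fit, json_path = NULL, draws_path = NULL) {
  stopifnot(inherits(fit, "posterior_draws"))
  summ <- lapply(c("B", "C", "E", "Z"), function(nm)
    as.list(stats::setNames(
      stats::quantile(fit$samples[[nm]], c(0.025, 0.5, 0.975), names = FALSE),
      c("q2.5", "median", "q97.5"))))
  names(summ) <- c("B", "C", "E", "Z")
  out <- list(scope = as.list(fit$fit_scope), parameters = summ,
              diagnostics = list(rhat = as.list(fit$diagnostics$rhat),
                                 ess = as.list(fit$diagnostics$ess)),
              converged = fit$converged, escalated = fit$escalated,
              fixed = fit$fixed, n_data_points = fit$n_data_points,
              retained_draws = nrow(fit$samples))
  if (!is.null(json_path))
    jsonlite::write_json(out, json_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  if (!is.null(draws_path))
    utils::write.csv(format(fit$samples, digits = 17, trim = TRUE,
                            scientific = FALSE),
                     draws_path, row.names = FALSE, quote = FALSE)
  invisible(out)
}

#' Read back a draws CSV written by \code{\link{write_fit_json}}
#'
#' @param path CSV path.
#' @return data frame with \code{chain}, \code{iteration}, \code{B},
#'   \code{C}, \code{E}, \code{Z}.
#' @export
read_draws_csv <- function(path) {
  df <- utils::read.csv(path)
  stopifnot(all(c("chain", "iteration", "B", "C", "E", "Z") %in% names(df)))
  df
}

#' Rebuild a posterior_draws object from a draws table
#'
#' Wraps a table of retained draws (e.g. from \code{\link{read_draws_csv}})
#' as a \code{posterior_draws} object so endpoint and variability functions
#' can run on deserialised fits. Convergence diagnostics are not recoverable
#' from the draws alone and are marked accordingly unless supplied.
#'
#' @param samples data frame with \code{chain}, \code{iteration}, \code{B},
#'   \code{C}, \code{E}, \code{Z}.
#' @param scope named character vector of scope labels.
#' @param converged convergence flag to carry (default \code{TRUE}).
#' @return a \code{posterior_draws} object.
#' @export
as_posterior_draws <- function(samples, scope = c(fit = "deserialised"),
                               converged = TRUE) {
  stopifnot(is.data.frame(samples),
            all(c("chain", "iteration", "B", "C", "E", "Z") %in% names(samples)),
            nrow(samples) >= 1L)
  structure(list(samples = samples,
                 diagnostics = list(rhat = NULL, ess = NULL),
                 converged = converged, escalated = NA,
                 fixed = list(), fit_scope = scope, config = NULL,
                 priors = NULL, n_data_points = NA_integer_),
            class = "posterior_draws")
}
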