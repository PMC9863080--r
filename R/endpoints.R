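#' Posterior distribution of a lethal (or oviposition-inhibiting) concentration
#'
#' Applies the closed-form inversion \code{\link{invert_lc}} to every
#' retained posterior draw, inducing the posterior of LC\eqn{_q} (or
#' OI\eqn{_q}), and summarises it by its median and central 95\% credible
#' interval. Summarising per draw (rather than inverting the median curve)
#' propagates the joint parameter uncertainty into the endpoint.
#'
#' @param draws a \code{posterior_draws} object from
#'   \code{\link{fit_dose_response}}.
#' @param q corrected response quantile in (0, 1), e.g. 0.5 for LC50.
#' @return list with \code{median}, \code{ci} (\code{c(lo, hi)}, central
#'   95\%), and the vector of per-draw values.
#' @export
lc_posterior <- function(draws, q) {
  stopifnot(inherits(draws, "posterior_draws"), length(q) == 1L,
            q > 0, q < 1)
  s <- draws$samples
  vals <- exp(s$C + log(expm1(-log1p(-q) / s$E)) / s$B)
  list(median = stats::median(vals),
       ci = stats::setNames(stats::quantile(vals, c(0.025, 0.975),
                                            names = FALSE), c("lo", "hi")),
       draws = vals)
}

#' Institution-level endpoint estimate with a replicate min-max range
#'
#' The point estimate is the posterior median LC\eqn{_q} of the fit pooled
#' over all of the institution's bioassays; its uncertainty range is the
#' minimum and maximum of the per-bioassay posterior medians. When only one
#' bioassay exists there is no between-replicate range, so the pooled fit's
#' 95\% credible interval is reported instead and the estimate is flagged as
#' a single-curve case.
#'
#' @param pooled \code{posterior_draws} of the pooled fit.
#' @param per_replicate list of \code{posterior_draws}, one per bioassay
#'   (may be empty).
#' @param q corrected response quantile in (0, 1).
#' @param endpoint_type \code{"LC"} or \code{"OI"}.
#' @return one-row data frame: scope labels, \code{q}, \code{value},
#'   \code{range_low}, \code{range_high}, \code{n_replicate_fits},
#'   \code{single_curve}, \code{range_available}, \code{endpoint_type}.
#' @export
institution_estimate <- function(pooled, per_replicate = list(), q,
                                 endpoint_type = c("LC", "OI")) {
  stopifnot(inherits(pooled, "posterior_draws"))
  endpoint_type <- match.arg(endpoint_type)
  pl <- lc_posterior(pooled, q)
  per_replicate <- Filter(function(f) isTRUE(f$converged), per_replicate)
  rep_medians <- vapply(per_replicate, function(f) lc_posterior(f, q)$median,
                        numeric(1))
  sc <- pooled$fit_scope
  lab <- function(nm) if (nm %in% names(sc)) unname(sc[nm]) else NA_character_
  if (length(rep_medians) >= 2L) {
    rng <- range(rep_medians)
    single <- FALSE; avail <- TRUE
  } else if (length(rep_medians) == 1L) {
    rng <- unname(pl$ci)
    single <- TRUE; avail <- TRUE
  } else {
    rng <- c(NA_real_, NA_real_)
    single <- TRUE; avail <- FALSE
  }
  data.frame(institution = lab("institution"), species = lab("species"),
             insecticide = lab("insecticide"), endpoint_type = endpoint_type,
             q = q, value = pl$median, range_low = rng[1], range_high = rng[2],
             n_replicate_fits = length(rep_medians), single_curve = single,
             range_available = avail, stringsAsFactors = FALSE)
}

#' Species-level summary across institutions
#'
#' Statistics at the insecticide-species level are the arithmetic mean of
#' the institution-level point estimates; the overall uncertainty range is
#' the envelope of the institution ranges (minimum of lows, maximum of
#' highs). With a single institution the summary degenerates to that
#' institution's estimate.
#'
#' @param estimates data frame of institution estimates
#'   (\code{\link{institution_estimate}} rows) for one species-insecticide
#'   combination and one \code{q}.
#' @return one-row data frame: \code{species}, \code{insecticide},
#'   \code{endpoint_type}, \code{q}, \code{value} (mean of institutions),
#'   \code{range_low}, \code{range_high}, \code{n_locations}.
#' @export
species_summary <- function(estimates) {
  stopifnot(is.data.frame(estimates), nrow(estimates) >= 1L)
  for (col in c("species", "insecticide", "endpoint_type", "q")) {
    if (length(unique(estimates[[col]])) > 1L)
      stop("cannot summarise estimates with mixed '", col, "'", call. = FALSE)
  }
  data.frame(species = estimates$species[1L],
             insecticide = estimates$insecticide[1L],
             endpoint_type = estimates$endpoint_type[1L],
             q = estimates$q[1L],
             value = mean(estimates$value),
             range_low = suppressWarnings(min(estimates$range_low, na.rm = TRUE)),
             range_high = suppressWarnings(max(estimates$range_high, na.rm = TRUE)),
             n_locations = nrow(estimates), stringsAsFactors = FALSE)
}

#' Discriminating concentration from a high lethal quantile
#'
#' A discriminating concentration is a fixed multiple (conventionally twice)
#' of a high lethal-concentration quantile of a susceptible colony --
#' LC99.9, or the LC99 basis used in recent bottle-bioassay practice. The
#' result is rounded to a conventional reporting precision.
#'
#' @param lc an institution/species estimate row from
#'   \code{\link{institution_estimate}} or \code{\link{species_summary}}, or
#'   a bare concentration.
#' @param multiplier positive multiple of the LC value (default 2).
#' @param allowed_q admissible LC bases when \code{lc} carries a \code{q}
#'   column (default LC99 and LC99.9).
#' @param signif_digits significant figures for reporting (default 2).
#' @return the discriminating concentration in \eqn{\mu}g/bottle.
#' @examples
#' compute_dc(3.5)  # 7
#' @export
compute_dc <- function(lc, multiplier = 2, allowed_q = c(0.99, 0.999),
                       signif_digits = 2) {
  if (multiplier <= 0) stop("'multiplier' must be positive", call. = FALSE)
  if (is.data.frame(lc)) {
    stopifnot(nrow(lc) == 1L)
    if (!lc$q %in% allowed_q)
      stop(sprintf("LC basis q = %g is not an admissible DC basis (%s)",
                   lc$q, paste(allowed_q, collapse = ", ")), call. = FALSE)
    value <- lc$value
  } else {
    stopifnot(is.numeric(lc), length(lc) == 1L, lc > 0)
    value <- lc
  }
  signif(multiplier * value, signif_digits)
}
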