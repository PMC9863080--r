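#' Per-iteration absolute deviation from the fitted curve
#'
#' For each retained posterior draw, the absolute difference between every
#' observed response proportion and the draw's fitted curve value at that
#' concentration, aggregated across data points, in percentage points.
#' Aggregation across points uses the mean by default (an average
#' within-bioassay deviation); a median-across-points mode is available
#' since the original summary convention is ambiguous on this step.
#' Deviations are computed on the raw probability scale: the fitted value
#' includes the background rate \code{Z}, matching the scale of the observed
#' proportions.
#'
#' @param draws a \code{posterior_draws} object.
#' @param data data frame of \code{x}, \code{n}, \code{y} triples (the same
#'   observations the model was fitted to). Rows with \code{n = 0} are
#'   excluded with a warning.
#' @param point_summary \code{"mean"} (default) or \code{"median"} across
#'   data points within one iteration.
#' @return numeric vector, one deviation (percentage points in
#'   \code{[0, 100]}) per retained draw.
#' @export
per_iteration_deviation <- function(draws, data,
                                    point_summary = c("mean", "median")) {
  stopifnot(inherits(draws, "posterior_draws"), is.data.frame(data),
            all(c("x", "n", "y") %in% names(data)), nrow(data) >= 1L)
  point_summary <- match.arg(point_summary)
  if (any(data$n == 0)) {
    warning("excluding ", sum(data$n == 0), " empty-trial row(s) (n = 0)")
    data <- data[data$n > 0, , drop = FALSE]
  }
  if (nrow(data) == 0L) stop("no usable data points", call. = FALSE)
  obs <- data$y / data$n
  s <- draws$samples
  lx <- ifelse(data$x > 0, log(data$x), NA_real_)
  # draws x points matrix of fitted probabilities
  p <- vapply(seq_len(nrow(data)), function(i) {
    if (data$x[i] == 0) return(s$Z)
    eta <- s$B * (lx[i] - s$C)
    1 - (1 - s$Z) * exp(-s$E * log1p_exp(eta))
  }, numeric(nrow(s)))
  if (!is.matrix(p)) p <- matrix(p, nrow = nrow(s))  # single-draw case
  dev <- abs(sweep(p, 2L, obs)) * 100
  if (point_summary == "mean") rowMeans(dev)
  else apply(dev, 1L, stats::median)
}

#' Within-bioassay variability of an institution's fit
#'
#' Summarises \code{\link{per_iteration_deviation}} by its median across
#' iterations -- the expected percentage-point departure of observed data
#' points from the best-fit line -- with the central 95\% interval of the
#' iteration deviations as its uncertainty.
#'
#' @inheritParams per_iteration_deviation
#' @param endpoint_type \code{"mortality"} or \code{"OI"}.
#' @return one-row data frame: scope labels, \code{value} (median,
#'   percentage points), \code{ci_low}, \code{ci_high},
#'   \code{endpoint_type}.
#' @export
within_bioassay_variability <- function(draws, data,
                                        point_summary = c("mean", "median"),
                                        endpoint_type = c("mortality", "OI")) {
  endpoint_type <- match.arg(endpoint_type)
  dev <- per_iteration_deviation(draws, data, point_summary)
  ci <- stats::quantile(dev, c(0.025, 0.975), names = FALSE)
  sc <- draws$fit_scope
  lab <- function(nm) if (nm %in% names(sc)) unname(sc[nm]) else NA_character_
  data.frame(institution = lab("institution"), species = lab("species"),
             insecticide = lab("insecticide"),
             value = stats::median(dev), ci_low = ci[1], ci_high = ci[2],
             endpoint_type = endpoint_type, stringsAsFactors = FALSE)
}

#' Aggregate within-bioassay variability across institutions
#'
#' Species-level variability is the mean of the institution-level values;
#' when several institutions contribute, the reported interval is their
#' minimum and maximum, and with a single institution the institution's own
#' 95\% interval is passed through.
#'
#' @param estimates data frame of rows from
#'   \code{\link{within_bioassay_variability}} sharing one
#'   species-insecticide scope.
#' @return one-row data frame: \code{species}, \code{insecticide},
#'   \code{value}, \code{ci_low}, \code{ci_high}, \code{n_locations},
#'   \code{endpoint_type}.
#' @export
aggregate_variability <- function(estimates) {
  stopifnot(is.data.frame(estimates), nrow(estimates) >= 1L)
  for (col in c("species", "insecticide", "endpoint_type")) {
    if (length(unique(estimates[[col]])) > 1L)
      stop("cannot aggregate estimates with mixed '", col, "'", call. = FALSE)
  }
  if (nrow(estimates) > 1L) {
    ci <- range(estimates$value)
  } else {
    ci <- c(estimates$ci_low, estimates$ci_high)
  }
  data.frame(species = estimates$species[1L],
             insecticide = estimates$insecticide[1L],
             value = mean(estimates$value), ci_low = ci[1], ci_high = ci[2],
             n_locations = nrow(estimates),
             endpoint_type = estimates$endpoint_type[1L],
             stringsAsFactors = FALSE)
}
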