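#' Concentration-response plot with replicate uncertainty ribbon
#'
#' One panel per species-insecticide combination: the pointwise posterior
#' median response curve of each institution's pooled fit (solid line), a
#' ribbon spanning the pointwise minimum and maximum of that institution's
#' per-bioassay median curves (absent, and annotated in the legend, when
#' only one replicate fit exists), and the observed pooled response
#' proportions sized by the number tested. Curves are drawn only across the
#' observed concentration range, on a log10-labelled axis in
#' \eqn{\mu}g/bottle.
#'
#' @param fits named list of pooled \code{posterior_draws} (one per
#'   institution scope), e.g. \code{analyze_campaign()$fits}.
#' @param replicate_fits list (parallel to \code{fits}) of per-bioassay fit
#'   lists; optional.
#' @param ds the \code{\link{bioassay_dataset}} that was fitted; optional,
#'   adds observed points.
#' @param n_grid curve evaluation points (default 100).
#' @return a \code{ggplot} object.
#' @export
plot_dose_response <- function(fits, replicate_fits = list(), ds = NULL,
                               n_grid = 100L) {
  stopifnot(is.list(fits), length(fits) >= 1L)
  median_curve <- function(fit, xs) {
    s <- fit$samples
    vapply(xs, function(x) {
      eta <- s$B * (log(x) - s$C)
      stats::median(1 - (1 - s$Z) * exp(-s$E * log1p_exp(eta)))
    }, numeric(1))
  }
  panels <- lapply(names(fits), function(id) {
    fit <- fits[[id]]
    sc <- fit$fit_scope
    xr <- attr(fit, "x_range")
    if (is.null(xr) && !is.null(ds)) {
      rec <- ds$records
      sel <- rec$institution == sc[["institution"]] &
        rec$species == sc[["species"]] &
        rec$insecticide == sc[["insecticide"]] &
        rec$concentration_ug_per_bottle > 0
      xr <- range(rec$concentration_ug_per_bottle[sel])
    }
    if (is.null(xr)) xr <- exp(stats::median(fit$samples$C) + c(-3, 3))
    xs <- exp(seq(log(xr[1]), log(xr[2]), length.out = n_grid))
    out <- data.frame(x = xs, p = median_curve(fit, xs),
                      institution = unname(sc["institution"]),
                      species = unname(sc["species"]),
                      insecticide = unname(sc["insecticide"]))
    reps <- replicate_fits[[id]]
    if (!is.null(reps) && length(reps) >= 2L) {
      curves <- vapply(reps, median_curve, numeric(length(xs)), xs = xs)
      out$p_min <- apply(curves, 1L, min)
      out$p_max <- apply(curves, 1L, max)
    } else {
      out$p_min <- NA_real_
      out$p_max <- NA_real_
    }
    out
  })
  curve_df <- do.call(rbind, panels)
  gg <- ggplot2::ggplot(curve_df, ggplot2::aes(x = x))
  if (any(!is.na(curve_df$p_min)))
    gg <- gg + ggplot2::geom_ribbon(
      ggplot2::aes(ymin = p_min, ymax = p_max,
                   fill = institution),
      alpha = 0.25, na.rm = TRUE)
  gg <- gg + ggplot2::geom_line(
    ggplot2::aes(y = p, colour = institution), linewidth = 0.8)
  if (!is.null(ds)) {
    rec <- ds$records[ds$records$concentration_ug_per_bottle > 0, , drop = FALSE]
    denom <- ifelse(rec$endpoint_type == "oviposition",
                    rec$n_chambered, rec$n_exposed)
    agg <- stats::aggregate(
      cbind(y = rec$n_responded, n = denom),
      by = list(x = rec$concentration_ug_per_bottle,
                institution = rec$institution, species = rec$species,
                insecticide = rec$insecticide),
      FUN = sum)
    agg$p_obs <- agg$y / agg$n
    gg <- gg + ggplot2::geom_point(
      data = agg,
      ggplot2::aes(x = x, y = p_obs, colour = institution,
                   size = n), alpha = 0.6)
  }
  gg + ggplot2::scale_x_log10() +
    ggplot2::facet_grid(species ~ insecticide) +
    ggplot2::labs(x = expression("Concentration ("*mu*"g/bottle)"),
                  y = "Response proportion",
                  colour = "Institution", fill = "Institution",
                  size = "Mosquitoes tested") +
    ggplot2::theme_bw()
}
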