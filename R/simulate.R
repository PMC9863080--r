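#' Bioassay campaign design
#'
#' Describes the layout of one laboratory's concentration-response campaign,
#' mirroring the standard two-step bottle-bioassay protocol: a bioassay
#' exposes mosquitoes at each of six serial concentrations in four replicate
#' bottles of 25, with two control bottles of 25, and the full series is run
#' in triplicate so each concentration accumulates ~300 mosquitoes.
#'
#' @param concentrations strictly increasing positive concentrations
#'   (\eqn{\mu}g/bottle); controls are added separately and must not appear
#'   here. Default: six half-log-spaced concentrations 0.1--30, the shape of
#'   a ten-fold serial-dilution series bracketing an LC50 near 1.
#' @param n_per_concentration mosquitoes per concentration within one
#'   bioassay (default 100, as 4 x 25).
#' @param replicates_per_concentration replicate bottles per concentration
#'   (default 4); must divide \code{n_per_concentration}.
#' @param n_control control mosquitoes per bioassay (default 50, as 2 x 25,
#'   split into bottles of the same size as treatment replicates).
#' @param n_bioassays number of complete series per laboratory (default 3).
#' @param overdispersion_rho intra-class correlation of the beta-binomial
#'   replicate-level overdispersion; 0 (default) gives pure binomial
#'   sampling.
#' @return object of class \code{campaign_design}.
#' @export
campaign_design <- function(concentrations = c(0.1, 0.3, 1, 3, 10, 30),
                            n_per_concentration = 100L,
                            replicates_per_concentration = 4L,
                            n_control = 50L, n_bioassays = 3L,
                            overdispersion_rho = 0) {
  stopifnot(length(concentrations) >= 1L, all(concentrations > 0),
            !is.unsorted(concentrations, strictly = TRUE),
            n_per_concentration >= 1L, replicates_per_concentration >= 1L,
            n_per_concentration %% replicates_per_concentration == 0L,
            n_control >= 1L, n_bioassays >= 1L,
            overdispersion_rho >= 0, overdispersion_rho < 1)
  structure(list(concentrations = concentrations,
                 n_per_concentration = as.integer(n_per_concentration),
                 replicates_per_concentration = as.integer(replicates_per_concentration),
                 n_control = as.integer(n_control),
                 n_bioassays = as.integer(n_bioassays),
                 overdispersion_rho = overdispersion_rho),
            class = "campaign_design")
}

# Replicate-level response probability: beta-draw around the curve value when
# overdispersed, degenerate otherwise. rho is the intra-class correlation of
# the implied beta-binomial.
replicate_probs <- function(p, k, rho) {
  if (rho <= 0 || p <= 0 || p >= 1) return(rep(p, k))
  nu <- (1 - rho) / rho   # a + b of the beta
  stats::rbeta(k, p * nu, (1 - p) * nu)
}

simulate_records <- function(curve, design, seed, institution, country,
                             species, strain, insecticide, endpoint_type,
                             recording_time_h, denominator_fun = NULL) {
  rep_size <- design$n_per_concentration %/% design$replicates_per_concentration
  ctrl_reps <- max(1L, as.integer(ceiling(design$n_control / rep_size)))
  ctrl_sizes <- rep(rep_size, ctrl_reps)
  ctrl_sizes[ctrl_reps] <- design$n_control - rep_size * (ctrl_reps - 1L)
  rows <- withr::with_seed(seed, {
    out <- list()
    for (b in seq_len(design$n_bioassays)) {
      bid <- sprintf("%s_%s_%s_b%02d", institution, insecticide, species, b)
      for (x in c(0, design$concentrations)) {
        is_ctrl <- x == 0
        sizes <- if (is_ctrl) ctrl_sizes else
          rep(rep_size, design$replicates_per_concentration)
        p <- mortality_curve(curve, x)
        pr <- replicate_probs(p, length(sizes), design$overdispersion_rho)
        n_resp <- stats::rbinom(length(sizes), sizes, pr)
        n_cham <- rep(NA_real_, length(sizes))
        n_exposed <- sizes
        if (endpoint_type == "oviposition") {
          n_cham <- denominator_fun(sizes)
          n_resp <- stats::rbinom(length(sizes), n_cham, pr)
        }
        out[[length(out) + 1L]] <- data.frame(
          institution = institution, country = country, species = species,
          strain = strain, insecticide = insecticide,
          endpoint_type = endpoint_type, bioassay_id = bid,
          replicate_id = sprintf("%s_%s_r%d", bid,
                                 if (is_ctrl) "ctrl" else formatC(x, format = "g"),
                                 seq_along(sizes)),
          concentration_ug_per_bottle = x, n_exposed = n_exposed,
          n_responded = n_resp, n_chambered = n_cham,
          recording_time_h = recording_time_h,
          stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, out)
  })
  rows
}

#' Simulate one laboratory's bioassay series from a known curve
#'
#' Draws binomial outcomes from a ground-truth concentration-response curve
#' under a \code{\link{campaign_design}}: for every bioassay, replicate
#' bottle and concentration \code{x}, deaths are
#' \code{Binomial(n, p(x))} with \code{p} from
#' \code{\link{mortality_curve}}; control bottles use \code{p = Z}. With
#' \code{overdispersion_rho > 0} each bottle's probability is first drawn
#' from a beta distribution with mean \code{p(x)} and intra-class
#' correlation \code{rho} (a beta-binomial mechanism). The same seed always
#' reproduces the same dataset.
#'
#' @param curve a \code{\link{curve_params}} ground truth.
#' @param design a \code{\link{campaign_design}}.
#' @param seed integer seed.
#' @param institution,country,species,strain,insecticide metadata labels.
#' @param recording_time_h recording time in hours (24 or 72).
#' @return a \code{\link{bioassay_dataset}}.
#' @export
simulate_bioassay <- function(curve, design = campaign_design(), seed,
                              institution = "LAB01", country = "XX",
                              species = "Ae. aegypti", strain = "lab-susceptible",
                              insecticide = "insecticide-A",
                              recording_time_h = 24L) {
  stopifnot(inherits(curve, "curve_params"), inherits(design, "campaign_design"))
  rows <- simulate_records(curve, design, seed, institution, country, species,
                           strain, insecticide, "mortality", recording_time_h)
  bioassay_dataset(rows, provenance = sprintf("simulated (seed %d)", seed))
}

#' Simulate a multi-laboratory campaign
#'
#' Concatenates per-laboratory simulations, one ground-truth curve per
#' laboratory, each run on an independent deterministic substream of the
#' master seed.
#'
#' @param curves_by_lab named list of \code{\link{curve_params}}; names are
#'   institution labels and must be unique.
#' @param design a \code{\link{campaign_design}} shared by all laboratories.
#' @param seed integer master seed.
#' @param ... further metadata passed to \code{\link{simulate_bioassay}}
#'   (species, insecticide, ...).
#' @return a \code{\link{bioassay_dataset}} spanning all laboratories.
#' @export
simulate_campaign <- function(curves_by_lab, design = campaign_design(), seed,
                              ...) {
  stopifnot(is.list(curves_by_lab), length(curves_by_lab) >= 1L)
  labs <- names(curves_by_lab)
  if (is.null(labs) || any(!nzchar(labs)))
    stop("curves_by_lab must be a named list of laboratory curves", call. = FALSE)
  if (anyDuplicated(labs))
    stop("duplicate laboratory labels: ",
         paste(unique(labs[duplicated(labs)]), collapse = ", "), call. = FALSE)
  seeds <- derive_seeds(seed, length(labs))
  parts <- lapply(seq_along(labs), function(k)
    simulate_bioassay(curves_by_lab[[k]], design, seed = seeds[k],
                      institution = labs[k], ...)$records)
  bioassay_dataset(do.call(rbind, parts),
                   provenance = sprintf("simulated campaign, %d labs (seed %d)",
                                        length(labs), seed))
}

#' Perturbed per-laboratory curves
#'
#' Generates between-laboratory heterogeneity around a base curve by
#' independent Gaussian perturbation of \code{log B}, \code{C} and (when
#' \code{Z > 0}) \code{logit Z}; \code{E} is left shared. A scale of 0
#' reproduces the base curve exactly, so all laboratories share the same
#' true LC values.
#'
#' @param base a \code{\link{curve_params}}.
#' @param labs character vector of laboratory labels.
#' @param scale standard deviation(s) of the perturbations, recycled over
#'   laboratories.
#' @param seed integer seed.
#' @return named list of \code{\link{curve_params}}.
#' @export
perturb_curves <- function(base, labs, scale = 0.1, seed) {
  stopifnot(inherits(base, "curve_params"), length(labs) >= 1L,
            all(scale >= 0))
  scale <- rep_len(scale, length(labs))
  withr::with_seed(seed, {
    out <- lapply(seq_along(labs), function(k) {
      s <- scale[k]
      if (s == 0) return(base)
      Z <- if (base$Z > 0)
        stats::plogis(stats::qlogis(base$Z) + stats::rnorm(1, 0, s))
      else 0
      curve_params(B = exp(log(base$B) + stats::rnorm(1, 0, s)),
                   C = base$C + stats::rnorm(1, 0, s),
                   E = base$E, Z = Z)
    })
    names(out) <- labs
    out
  })
}

#' Simulate an oviposition-inhibition bioassay series
#'
#' Emulates the sterilizing-compound protocol: exposed females are held, and
#' surviving females are individually chambered; the number \emph{not}
#' ovipositing among those chambered follows the same logistic
#' concentration-response form, with background non-laying
#' \code{Z = 1 - control_laying_rate}. Chambered survivor counts are drawn
#' binomially with survival probability \code{chambering_rate}.
#'
#' @param curve a \code{\link{curve_params}} whose \code{Z} is ignored and
#'   replaced by \code{1 - control_laying_rate}.
#' @param control_laying_rate proportion of control females expected to lay,
#'   in (0, 1].
#' @param design a \code{\link{campaign_design}}.
#' @param seed integer seed.
#' @param chambering_rate probability an exposed female survives to
#'   chambering (default 0.9).
#' @param institution,country,species,strain,insecticide metadata labels.
#' @return a \code{\link{bioassay_dataset}} with
#'   \code{endpoint_type = "oviposition"}.
#' @export
simulate_oviposition <- function(curve, control_laying_rate,
                                 design = campaign_design(), seed,
                                 chambering_rate = 0.9,
                                 institution = "LAB01", country = "XX",
                                 species = "An. gambiae",
                                 strain = "lab-susceptible",
                                 insecticide = "pyriproxyfen") {
  stopifnot(control_laying_rate > 0, control_laying_rate <= 1,
            chambering_rate > 0, chambering_rate <= 1)
  ovi_curve <- curve_params(B = curve$B, C = curve$C, E = curve$E,
                            Z = 1 - control_laying_rate)
  denominator_fun <- function(sizes)
    pmax(1L, stats::rbinom(length(sizes), sizes, chambering_rate))
  rows <- simulate_records(ovi_curve, design, seed, institution, country,
                           species, strain, insecticide, "oviposition",
                           recording_time_h = 168L,
                           denominator_fun = denominator_fun)
  bioassay_dataset(rows, provenance = sprintf("simulated oviposition (seed %d)",
                                              seed))
}
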