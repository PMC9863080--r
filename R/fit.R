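#' Prior specification for the curve parameters
#'
#' Normal priors, truncated to each parameter's support: the slope \code{B}
#' and asymmetry \code{E} are strictly positive and the background rate
#' \code{Z} is a probability, so their priors are normals restricted to
#' \code{(0, Inf)} and \code{[0, 1)} respectively; the location \code{C} is
#' unrestricted on the log-concentration scale. Defaults are
#' \code{B ~ N(3, 1)}, \code{C ~ N(3, 5)}, \code{E ~ N(3, 5)},
#' \code{Z ~ N(0, 5)} (mean, sd).
#'
#' @param B,C,E,Z length-2 numeric vectors \code{c(mean, sd)}.
#' @return object of class \code{prior_spec}: per-parameter mean, sd and
#'   truncation bounds.
#' @export
prior_spec <- function(B = c(3, 1), C = c(3, 5), E = c(3, 5), Z = c(0, 5)) {
  mk <- function(ms, lower, upper) {
    stopifnot(is.numeric(ms), length(ms) == 2L, ms[2] > 0)
    list(mean = ms[1], sd = ms[2], lower = lower, upper = upper)
  }
  structure(list(
    B = mk(B, 0, Inf),
    C = mk(C, -Inf, Inf),
    E = mk(E, 0, Inf),
    Z = mk(Z, 0, 1)
  ), class = "prior_spec")
}

# Unnormalised log prior density (truncation constants are parameter-free and
# cancel in any posterior normalisation).
log_prior <- function(params, priors) {
  total <- 0
  for (nm in c("B", "C", "E", "Z")) {
    pr <- priors[[nm]]
    v <- params[[nm]]
    if (v < pr$lower || v >= pr$upper && is.finite(pr$upper)) return(-Inf)
    if (v > pr$upper) return(-Inf)
    total <- total + stats::dnorm(v, pr$mean, pr$sd, log = TRUE)
  }
  total
}

#' MCMC sampling schedule
#'
#' Default schedule: four chains of 5000 iterations each with the first 50\%
#' discarded as warm-up. If any parameter's potential scale reduction factor
#' is at or above \code{rhat_threshold} after the first run, the model is
#' refitted once with \code{escalation_iterations} (default 10,000)
#' iterations; there is no second escalation.
#'
#' @param chains number of chains.
#' @param iterations iterations per chain (even).
#' @param warmup_fraction fraction of iterations discarded as warm-up.
#' @param escalation_iterations iterations used in the single refit when the
#'   first run has not converged.
#' @param rhat_threshold convergence criterion on the potential scale
#'   reduction factor of every free parameter.
#' @param adapt additional sampler-adaptation steps before the schedule
#'   proper (not counted in \code{iterations}).
#' @param seed integer master seed; all chain random streams derive from it.
#' @return object of class \code{mcmc_config}.
#' @export
mcmc_config <- function(chains = 4L, iterations = 5000L, warmup_fraction = 0.5,
                        escalation_iterations = 10000L, rhat_threshold = 1.05,
                        adapt = 1000L, seed = 1L) {
  stopifnot(chains >= 1L, iterations >= 2L, iterations %% 2L == 0L,
            warmup_fraction > 0, warmup_fraction < 1,
            escalation_iterations >= iterations, rhat_threshold > 1)
  structure(list(chains = as.integer(chains), iterations = as.integer(iterations),
                 warmup_fraction = warmup_fraction,
                 escalation_iterations = as.integer(escalation_iterations),
                 rhat_threshold = rhat_threshold, adapt = as.integer(adapt),
                 seed = as.integer(seed)),
            class = "mcmc_config")
}

# Deterministic sub-seeds from a master seed; keeps every derived seed well
# below 2^31.
derive_seeds <- function(seed, n) {
  withr::with_seed(as.integer(seed) %% .Machine$integer.max,
                   sample.int(.Machine$integer.max - 1L, n))
}

jags_model_string <- function(has_treated, has_controls, fixed, priors) {
  prior_line <- function(nm) {
    pr <- priors[[nm]]
    tau <- 1 / pr$sd^2
    trunc <- if (nm %in% c("B", "E")) " T(0,)"
    else if (nm == "Z") " T(0, 0.999999)"
    else ""
    sprintf("  %s ~ dnorm(%.10g, %.10g)%s", nm, pr$mean, tau, trunc)
  }
  lines <- c("model {")
  if (has_treated) lines <- c(lines,
    "  for (i in 1:Nt) {",
    # clamp away from {0, 1} so dispersed initial values cannot make an
    # observed count numerically impossible
    "    pr[i] <- 1 - (1 - Z) * pow(1 + exp(B * (lx[i] - C)), -E)",
    "    p[i] <- max(1.0E-12, min(1 - 1.0E-12, pr[i]))",
    "    y[i] ~ dbin(p[i], n[i])",
    "  }")
  if (has_controls) lines <- c(lines,
    "  for (j in 1:Nc) {",
    "    yc[j] ~ dbin(Z, nc[j])",
    "  }")
  for (nm in c("B", "C", "E", "Z")) {
    lines <- c(lines, if (nm %in% names(fixed))
      sprintf("  %s <- %.10g", nm, fixed[[nm]])
      else prior_line(nm))
  }
  paste(c(lines, "}"), collapse = "\n")
}

# One complete JAGS run of the schedule; returns retained draws and
# diagnostics. Initial values are drawn from the priors so chains start
# dispersed.
run_jags_once <- function(data, priors, fixed, chains, iterations,
                          warmup_fraction, adapt, seeds) {
  treated <- data[data$x > 0, , drop = FALSE]
  controls <- data[data$x == 0, , drop = FALSE]
  model_txt <- jags_model_string(nrow(treated) > 0L, nrow(controls) > 0L,
                                 fixed, priors)
  jd <- list()
  if (nrow(treated)) jd <- c(jd, list(Nt = nrow(treated), lx = log(treated$x),
                                      n = as.integer(treated$n),
                                      y = as.integer(treated$y)))
  if (nrow(controls)) jd <- c(jd, list(Nc = nrow(controls),
                                       nc = as.integer(controls$n),
                                       yc = as.integer(controls$y)))
  free <- setdiff(c("B", "C", "E", "Z"), names(fixed))
  inits <- lapply(seq_len(chains), function(ch) {
    ini <- withr::with_seed(seeds[ch], {
      draw <- list(
        B = abs(stats::rnorm(1, priors$B$mean, priors$B$sd)) + 1e-3,
        C = stats::rnorm(1, priors$C$mean, priors$C$sd),
        E = abs(stats::rnorm(1, priors$E$mean, priors$E$sd)) + 1e-3,
        Z = stats::runif(1, 0, 0.5)
      )
      draw[free]
    })
    c(ini, list(.RNG.name = "base::Mersenne-Twister",
                .RNG.seed = seeds[ch]))
  })
  warmup <- as.integer(round(iterations * warmup_fraction))
  retained <- iterations - warmup
  model <- rjags::jags.model(textConnection(model_txt), data = jd,
                             inits = inits, n.chains = chains,
                             n.adapt = adapt, quiet = TRUE)
  stats::update(model, n.iter = warmup, progress.bar = "none")
  samp <- rjags::coda.samples(model, variable.names = free,
                              n.iter = retained, progress.bar = "none")
  rhat <- if (chains > 1L) {
    gd <- try(coda::gelman.diag(samp, autoburnin = FALSE,
                                multivariate = FALSE), silent = TRUE)
    if (inherits(gd, "try-error")) stats::setNames(rep(NA_real_, length(free)), free)
    else stats::setNames(gd$psrf[, 1L][free], free)
  } else stats::setNames(rep(NA_real_, length(free)), free)
  ess <- stats::setNames(as.numeric(coda::effectiveSize(samp))[
    match(free, coda::varnames(samp))], free)
  draws <- do.call(rbind, lapply(seq_along(samp), function(ch) {
    m <- as.matrix(samp[[ch]])
    df <- as.data.frame(m)[, free, drop = FALSE]
    for (nm in names(fixed)) df[[nm]] <- fixed[[nm]]
    data.frame(chain = ch, iteration = seq_len(nrow(m)),
               df[, c("B", "C", "E", "Z")])
  }))
  rownames(draws) <- NULL
  list(draws = draws, rhat = rhat, ess = ess, retained = retained * chains)
}

#' Fit the Bayesian binomial 5PL concentration-response model
#'
#' Samples the posterior of the curve parameters \code{B}, \code{C},
#' \code{E}, \code{Z} given exposure records, using a binomial likelihood
#' with the five-parameter logistic mean curve (asymptotes fixed at 0 and 1)
#' and truncated-normal priors (\code{\link{prior_spec}}). Control records
#' (\code{x = 0}) enter the likelihood through the background parameter
#' \code{Z}, so control-mortality correction happens inside the model.
#' Every exposure record is one data point of the likelihood; records are
#' not pooled across replicates before fitting.
#'
#' Convergence is assessed with the potential scale reduction factor across
#' chains; if any free parameter's factor is at or above
#' \code{config$rhat_threshold}, the model is automatically refitted once
#' with \code{config$escalation_iterations} iterations, and the returned
#' \code{converged} flag reflects that final run.
#'
#' @param data a \code{\link{bioassay_dataset}}, or a data frame of triples
#'   \code{x} (concentration), \code{n} (tested), \code{y} (responded). An
#'   empty (zero-row) data frame is allowed and yields a prior-only fit.
#' @param priors a \code{\link{prior_spec}}.
#' @param config an \code{\link{mcmc_config}}.
#' @param fixed named list of parameters to hold fixed (e.g.
#'   \code{list(E = 1, Z = 0)} for the symmetric no-background reduced model).
#' @param scope named character vector of labels (institution, species,
#'   insecticide, optionally bioassay_id) identifying what was fitted.
#' @return object of class \code{posterior_draws}: \code{samples} (data frame
#'   with \code{chain}, \code{iteration}, \code{B}, \code{C}, \code{E},
#'   \code{Z}), \code{diagnostics} (\code{rhat}, \code{ess} per free
#'   parameter, for the final run), \code{converged}, \code{escalated},
#'   \code{fit_scope}, and the configuration used.
#' @examples
#' \dontrun{
#' cp <- curve_params(3, 0, 1, 0.03)
#' ds <- simulate_bioassay(cp, campaign_design(), seed = 1)
#' fit <- fit_dose_response(ds, config = mcmc_config(iterations = 1000))
#' }
#' @export
fit_dose_response <- function(data, priors = prior_spec(),
                              config = mcmc_config(), fixed = list(),
                              scope = c(fit = "unspecified")) {
  if (inherits(data, "bioassay_dataset")) data <- fit_data(data)
  stopifnot(is.data.frame(data))
  if (nrow(data) > 0L) {
    stopifnot(all(c("x", "n", "y") %in% names(data)),
              all(data$x >= 0), all(data$y <= data$n))
    if (length(unique(data$x[data$x > 0])) < 2L)
      warning("fewer than 2 distinct treated concentrations; the curve is weakly identified")
  }
  stopifnot(inherits(priors, "prior_spec"), inherits(config, "mcmc_config"))
  if (length(fixed)) stopifnot(all(names(fixed) %in% c("B", "C", "E", "Z")))
  seeds <- derive_seeds(config$seed, 2L * config$chains)
  first <- run_jags_once(data, priors, fixed, config$chains,
                         config$iterations, config$warmup_fraction,
                         config$adapt, seeds[seq_len(config$chains)])
  threshold_ok <- function(run) {
    r <- run$rhat
    length(r) == 0L || (all(is.finite(r)) && all(r < config$rhat_threshold))
  }
  escalated <- FALSE
  final <- first
  if (!threshold_ok(first)) {
    escalated <- TRUE
    final <- run_jags_once(data, priors, fixed, config$chains,
                           config$escalation_iterations,
                           config$warmup_fraction, config$adapt,
                           seeds[config$chains + seq_len(config$chains)])
  }
  if (nrow(final$draws) == 0L)
    stop("sampler returned no draws", call. = FALSE)
  structure(list(
    samples = final$draws,
    diagnostics = list(rhat = final$rhat, ess = final$ess,
                       first_run_rhat = first$rhat),
    converged = threshold_ok(final),
    escalated = escalated,
    fixed = fixed,
    fit_scope = scope,
    config = config,
    priors = priors,
    n_data_points = nrow(data)
  ), class = "posterior_draws")
}

#' @export
print.posterior_draws <- function(x, ...) {
  cat(sprintf("posterior_draws: %d retained draws (%d chains)\n",
              nrow(x$samples), max(x$samples$chain)))
  cat("  scope:", paste(names(x$fit_scope), x$fit_scope, sep = "=",
                        collapse = ", "), "\n")
  qs <- t(vapply(c("B", "C", "E", "Z"), function(nm)
    stats::quantile(x$samples[[nm]], c(0.025, 0.5, 0.975)), numeric(3)))
  colnames(qs) <- c("2.5%", "median", "97.5%")
  print(round(qs, 4))
  cat(sprintf("  converged: %s%s  max rhat: %.4g\n", x$converged,
              if (x$escalated) " (after escalation)" else "",
              suppressWarnings(max(x$diagnostics$rhat, na.rm = TRUE))))
  invisible(x)
}

#' Fit one curve per individual bioassay
#'
#' Fits the model separately to each bioassay (one concentration series run
#' on one occasion), producing the replicate-level curves whose endpoint
#' medians form the min-max uncertainty range around the pooled estimate.
#' Bioassays failing QC should be removed beforehand
#' (\code{\link{apply_qc}}); a group whose fit errors is skipped with a
#' warning rather than aborting the batch.
#'
#' @param ds a \code{\link{bioassay_dataset}}.
#' @param priors a \code{\link{prior_spec}}.
#' @param config an \code{\link{mcmc_config}}; each bioassay receives a
#'   deterministic sub-seed of \code{config$seed}.
#' @param fixed named list of parameters to hold fixed.
#' @return named list of \code{posterior_draws}, one per bioassay id.
#' @export
fit_per_replicate <- function(ds, priors = prior_spec(),
                              config = mcmc_config(), fixed = list()) {
  stopifnot(inherits(ds, "bioassay_dataset"))
  rec <- ds$records
  key <- interaction(rec[BIOASSAY_KEYS], drop = TRUE, sep = "\r")
  groups <- split(seq_len(nrow(rec)), key)
  seeds <- derive_seeds(config$seed, length(groups))
  fits <- vector("list", length(groups))
  names(fits) <- vapply(groups, function(idx) rec$bioassay_id[idx[1L]], "")
  for (k in seq_along(groups)) {
    g <- rec[groups[[k]], , drop = FALSE]
    cfg <- config
    cfg$seed <- seeds[k]
    scope <- c(institution = g$institution[1L], species = g$species[1L],
               insecticide = g$insecticide[1L], bioassay_id = g$bioassay_id[1L])
    fits[[k]] <- tryCatch(
      fit_dose_response(fit_data(g), priors = priors, config = cfg,
                        fixed = fixed, scope = scope),
      error = function(e) {
        warning(sprintf("skipping bioassay '%s': %s",
                        g$bioassay_id[1L], conditionMessage(e)))
        NULL
      })
  }
  Filter(Negate(is.null), fits)
}

#' Grid approximation of the posterior (testing oracle)
#'
#' Enumerates the posterior over a rectangular parameter grid by direct
#' evaluation of likelihood times prior, normalised with a log-sum-exp
#' rescaling. Exact up to grid resolution and fully independent of the MCMC
#' path, which makes it the reference against which the sampler is checked
#' on small problems.
#'
#' @param data data frame of \code{x}, \code{n}, \code{y} triples.
#' @param priors a \code{\link{prior_spec}}.
#' @param grid named list of numeric vectors, one per free parameter (subset
#'   of \code{B}, \code{C}, \code{E}, \code{Z}); total cells must not exceed
#'   \code{max_cells}.
#' @param fixed named list of values for the remaining parameters.
#' @param max_cells guard on grid size (default 1e6).
#' @return list with \code{cells} (data frame of parameter values and
#'   normalised posterior \code{mass}), \code{means} (marginal posterior
#'   means) and \code{quantiles} (marginal 2.5/50/97.5\% quantiles).
#' @export
grid_posterior <- function(data, priors = prior_spec(), grid, fixed = list(),
                           max_cells = 1e6) {
  stopifnot(is.list(grid), length(grid) >= 1L,
            all(names(grid) %in% c("B", "C", "E", "Z")))
  free <- names(grid)
  if (!setequal(c(free, names(fixed)), c("B", "C", "E", "Z")))
    stop("grid plus fixed must cover exactly B, C, E, Z", call. = FALSE)
  cells <- expand.grid(grid, KEEP.OUT.ATTRS = FALSE)
  if (nrow(cells) > max_cells) stop("grid too large to enumerate", call. = FALSE)
  logpost <- vapply(seq_len(nrow(cells)), function(i) {
    par <- c(as.list(cells[i, , drop = FALSE]), fixed)
    lp <- log_prior(par, priors)
    if (!is.finite(lp)) return(-Inf)
    ll <- if (nrow(data)) log_likelihood(par, data) else 0
    lp + ll
  }, numeric(1))
  m <- max(logpost)
  if (!is.finite(m)) stop("posterior mass is zero everywhere on the grid; data and prior incompatible", call. = FALSE)
  w <- exp(logpost - m)
  mass <- w / sum(w)
  cells$mass <- mass
  means <- vapply(free, function(nm) sum(cells[[nm]] * mass), numeric(1))
  quantiles <- lapply(free, function(nm) {
    o <- order(cells[[nm]])
    v <- cells[[nm]][o]
    cm <- cumsum(mass[o])
    vapply(c(0.025, 0.5, 0.975), function(q) v[which(cm >= q)[1L]], numeric(1))
  })
  names(quantiles) <- free
  quantiles <- lapply(quantiles, function(v)
    stats::setNames(v, c("2.5%", "50%", "97.5%")))
  list(cells = cells, means = means, quantiles = quantiles)
}
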