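#' Concentration-response curve parameters
#'
#' Constructs the parameter set of the binomial five-parameter logistic
#' concentration-response model used throughout the package. The response
#' probability at concentration \eqn{x} (\eqn{\mu}g active ingredient per
#' bottle) is
#' \deqn{p(x) = D + \frac{A - (D - Z)}{[1 + e^{B(\ln x - C)}]^E}}
#' with the lower and upper asymptotes fixed at \eqn{A = 0} and \eqn{D = 1},
#' so that \eqn{p(x) = 1 - (1 - Z)/[1 + e^{B(\ln x - C)}]^E}. \eqn{Z} is the
#' background response rate (control mortality, or control non-laying for
#' oviposition endpoints): the curve approaches \eqn{Z} as \eqn{x \to 0} and
#' 1 as \eqn{x \to \infty}.
#'
#' @param B slope, strictly positive.
#' @param C location on the natural-log concentration scale:
#'   \code{exp(C)} is the concentration of 50\% background-corrected response
#'   when \code{E = 1}.
#' @param E asymmetry, strictly positive; \code{E = 1} gives the symmetric
#'   four-parameter logistic.
#' @param Z background response rate in \code{[0, 1)}.
#' @return An object of class \code{curve_params} (a named list with fields
#'   \code{B}, \code{C}, \code{E}, \code{Z} and the fixed asymptotes
#'   \code{A = 0}, \code{D = 1}).
#' @examples
#' cp <- curve_params(B = 3, C = 0, E = 1, Z = 0.03)
#' mortality_curve(cp, c(0, 1, 10))
#' @export
curve_params <- function(B, C, E = 1, Z = 0) {
  for (nm in c("B", "C", "E", "Z")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop(sprintf("'%s' must be a single finite number", nm), call. = FALSE)
  }
  if (B <= 0) stop("slope 'B' must be > 0", call. = FALSE)
  if (E <= 0) stop("asymmetry 'E' must be > 0", call. = FALSE)
  if (Z < 0 || Z >= 1) stop("background rate 'Z' must be in [0, 1)", call. = FALSE)
  structure(list(B = B, C = C, E = E, Z = Z, A = 0, D = 1),
            class = "curve_params")
}

#' @export
print.curve_params <- function(x, ...) {
  cat("5PL concentration-response curve (A = 0, D = 1 fixed)\n")
  cat(sprintf("  B = %.4g  C = %.4g  E = %.4g  Z = %.4g\n", x$B, x$C, x$E, x$Z))
  invisible(x)
}

# log(1 + exp(x)) without overflow
log1p_exp <- function(x) {
  out <- x
  small <- x <= 30
  out[small] <- log1p(exp(x[small]))
  out
}

#' Evaluate the concentration-response curve
#'
#' Response probability at one or more concentrations. \code{x = 0} (solvent
#' control) returns the limiting value \code{Z}, so control observations can
#' be scored against the same curve.
#'
#' @param params a \code{\link{curve_params}} object, or a list/one-row data
#'   frame with elements \code{B}, \code{C}, \code{E}, \code{Z}.
#' @param x numeric vector of concentrations (\eqn{\mu}g/bottle), all
#'   \code{>= 0}.
#' @return numeric vector of response probabilities in \code{[Z, 1)}.
#' @examples
#' mortality_curve(curve_params(3, 0), 1)       # 0.5 at the midpoint
#' mortality_curve(curve_params(2, log(2), 2, 0.1), 2)  # 1 - 0.9/4
#' @export
mortality_curve <- function(params, x) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0))
    stop("'x' must be finite non-negative concentrations", call. = FALSE)
  p <- rep(params$Z, length(x))
  pos <- x > 0
  if (any(pos)) {
    eta <- params$B * (log(x[pos]) - params$C)
    p[pos] <- 1 - (1 - params$Z) * exp(-params$E * log1p_exp(eta))
  }
  p
}

#' Invert the curve: concentration for a target corrected response
#'
#' Solves for the concentration at which the background-corrected response
#' \eqn{(p(x) - Z)/(1 - Z)} equals \code{q}. This is the LC\eqn{_q} (or
#' OI\eqn{_q}) of the curve: the reported dose-response relationship is the
#' estimated response without the background rate \code{Z}, so lethal
#' concentrations are defined on that corrected scale. Closed form:
#' \deqn{x_q = \exp\!\left(C + \frac{\ln[(1-q)^{-1/E} - 1]}{B}\right)}
#'
#' @param params a \code{\link{curve_params}} object (or compatible list).
#' @param q target corrected response proportion(s), each in (0, 1).
#' @return concentration(s) in \eqn{\mu}g/bottle; strictly increasing in
#'   \code{q}.
#' @examples
#' invert_lc(curve_params(3, 0), 0.5)    # exp(C) = 1 when E = 1
#' invert_lc(curve_params(3, 0), 0.99)   # 99^(1/3)
#' @export
invert_lc <- function(params, q) {
  if (!is.numeric(q) || any(!is.finite(q)) || any(q <= 0) || any(q >= 1))
    stop("'q' must lie strictly between 0 and 1", call. = FALSE)
  exp(params$C + log(expm1(-log1p(-q) / params$E)) / params$B)
}

#' Binomial log-likelihood of pooled bioassay observations
#'
#' Sum of binomial log-probabilities of the observed counts under the curve.
#' Each observation is one exposure unit: \code{n} mosquitoes tested at
#' concentration \code{x} with \code{y} responding. Control rows enter with
#' \code{x = 0}, where the curve evaluates to \code{Z}: background correction
#' is part of the model rather than a pre-processing step. A structurally
#' impossible configuration (e.g. \code{Z = 0} with control deaths) yields
#' \code{-Inf}, not an error. Empty trials (\code{n = 0}) contribute zero.
#'
#' @param params a \code{\link{curve_params}} object.
#' @param data data frame with numeric columns \code{x} (concentration,
#'   \eqn{\mu}g/bottle; 0 = control), \code{n} (tested) and \code{y}
#'   (responded).
#' @return the log-likelihood, a single (possibly \code{-Inf}) number.
#' @examples
#' log_likelihood(curve_params(3, 0), data.frame(x = 1, n = 2, y = 1))
#' @export
log_likelihood <- function(params, data) {
  stopifnot(is.data.frame(data), all(c("x", "n", "y") %in% names(data)))
  if (nrow(data) == 0L) stop("'data' must contain at least one observation", call. = FALSE)
  if (any(data$y > data$n) || any(data$y < 0) || any(data$n < 0))
    stop("counts must satisfy 0 <= y <= n", call. = FALSE)
  p <- mortality_curve(params, data$x)
  sum(stats::dbinom(data$y, data$n, p, log = TRUE))
}
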