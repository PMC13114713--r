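#' Weighted tail neighborhood of a GPD
#'
#' Specifies the contamination neighborhood
#' \deqn{V_\epsilon(F) = \{G : \sup_x |\bar F(x) - \bar G(x)|\, w(x) \le \epsilon\}}
#' around a GPD center `F`, with an increasing weight `w` diverging at
#' infinity, so large departures in the right tail are not tolerated.  The
#' default weight is `w(x) = 1 + x`.
#'
#' @param epsilon contamination radius (>= 0).
#' @param weight increasing positive weight function of one argument.
#' @return An object of class `"neighborhood_spec"`.
#' @export
neighborhood_spec <- function(epsilon, weight = function(x) 1 + x) {
  stopifnot(is.numeric(epsilon), length(epsilon) == 1L, is.function(weight))
  if (epsilon < 0) stop("'epsilon' must be nonnegative", call. = FALSE)
  structure(list(epsilon = epsilon, weight = weight),
            class = "neighborhood_spec")
}

#' Bounds on a conditional survival probability over a GPD neighborhood
#'
#' For any distribution in the neighborhood, the conditional survival
#' \eqn{\bar G(x)/\bar G(s)} is bracketed by
#' \deqn{\frac{\bar F(x) - \epsilon/w(x)}{\bar F(s) + \epsilon/w(s)}
#'   \;\le\; \frac{\bar G(x)}{\bar G(s)} \;\le\;
#'   \frac{\bar F(x) + \epsilon/w(x)}{\bar F(s) - \epsilon/w(s)},}
#' with \eqn{\bar F} the GPD survival function; the lower bound is clipped at
#' 0 and the upper at 1.  At `epsilon = 0` both bounds collapse to the exact
#' GPD conditional probability.
#'
#' @param x,s evaluation point and conditioning threshold, `x >= s >= 0`.
#' @param params a [gpd_params()] object (the neighborhood center).
#' @param nb a [neighborhood_spec()].
#' @return Named numeric `c(lower, upper)`.
#' @export
conditional_sf_bounds <- function(x, s, params, nb) {
  stopifnot(inherits(params, "gpd_params"), inherits(nb, "neighborhood_spec"))
  if (!(s >= 0 && x >= s)) stop("must have x >= s >= 0", call. = FALSE)
  fx <- gpd_sf(x, params); fs <- gpd_sf(s, params)
  ex <- nb$epsilon / nb$weight(x); es <- nb$epsilon / nb$weight(s)
  if (fs <= es)
    stop("infeasible neighborhood: survival at the threshold is swamped by the contamination radius",
         call. = FALSE)
  c(lower = max(0, (fx - ex) / (fs + es)),
    upper = min(1, (fx + ex) / (fs - es)))
}

#' First-order relative-error bound under GPD contamination
#'
#' For small `epsilon`, the ratio of the contaminated to the exact GPD
#' conditional survival lies in \eqn{[1 - u(s,x)\epsilon,\; 1 + u(s,x)\epsilon]}
#' with
#' \deqn{u(s,x) = \frac{(1 + cs/a)^{1/c}}{w(s)} + \frac{(1 + cx/a)^{1/c}}{w(x)}}
#' (symmetric in its arguments).
#'
#' @param x,s evaluation point and conditioning threshold (the coefficient is
#'   symmetric in its two arguments, so their order is immaterial); both
#'   nonnegative.
#' @param params a [gpd_params()] object (the neighborhood center).
#' @param nb a [neighborhood_spec()].
#' @return The nonnegative coefficient `u(s, x)`.
#' @export
relative_error_bound_u <- function(s, x, params, nb) {
  stopifnot(inherits(params, "gpd_params"), inherits(nb, "neighborhood_spec"))
  if (s < 0 || x < 0) stop("'s' and 'x' must be nonnegative", call. = FALSE)
  cc <- params$c; aa <- params$a
  (1 + cc * s / aa)^(1 / cc) / nb$weight(s) +
    (1 + cc * x / aa)^(1 / cc) / nb$weight(x)
}

#' Smallest threshold meeting a prescribed misspecification tolerance
#'
#' Finds the smallest conditioning threshold `s` such that the first-order
#' relative error on conditional probabilities up to `x` stays below
#' `delta_tol`:
#' \deqn{\frac{(1 + cs/a)^{1/c}}{w(s)} \le \frac{\delta}{\epsilon} -
#'   \frac{(1 + cx/a)^{1/c}}{w(x)}.}
#' The search scans `[0, 1e6]` on a log-spaced bracket and refines the first
#' feasible crossing by bisection.  The left-hand side need not be monotone
#' (for the default weight it is constant when `c = 1, a = 1`), so the scan is
#' exhaustive rather than assuming a single crossing.
#'
#' @param params a [gpd_params()] object.
#' @param nb a [neighborhood_spec()] with strictly positive `epsilon`.
#' @param delta_tol prescribed relative-error tolerance (> 0).
#' @param x evaluation point bounding the conditional probabilities of
#'   interest.
#' @param s_max upper end of the search range (default `1e6`).
#' @return A list with `s` (the minimal feasible threshold, or `NA`) and
#'   `feasible` (logical).
#' @export
threshold_for_tolerance <- function(params, nb, delta_tol, x, s_max = 1e6) {
  stopifnot(inherits(params, "gpd_params"), inherits(nb, "neighborhood_spec"))
  if (nb$epsilon <= 0) stop("'epsilon' must be strictly positive here", call. = FALSE)
  if (delta_tol <= 0) stop("'delta_tol' must be strictly positive", call. = FALSE)
  cc <- params$c; aa <- params$a
  rhs <- delta_tol / nb$epsilon - (1 + cc * x / aa)^(1 / cc) / nb$weight(x)
  lhs <- function(s) (1 + cc * s / aa)^(1 / cc) / nb$weight(s)
  if (rhs <= 0) return(list(s = NA_real_, feasible = FALSE))
  grid <- c(0, exp(seq(log(1e-6), log(s_max), length.out = 1000)))
  ok <- lhs(grid) <= rhs
  if (!any(ok)) return(list(s = NA_real_, feasible = FALSE))
  i <- which(ok)[1]
  if (i == 1L) return(list(s = 0, feasible = TRUE))
  root <- stats::uniroot(function(s) lhs(s) - rhs,
                         lower = grid[i - 1], upper = grid[i],
                         tol = 1e-10)$root
  list(s = root, feasible = TRUE)
}
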