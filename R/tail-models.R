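#' Generalized Pareto parameters
#'
#' Container for the tail index `c` and scale `a` of the generalized Pareto
#' distribution (GPD) used to model the reciprocal resistance
#' \eqn{\tilde R = 1/R}.  The survival function is
#' \deqn{\bar F_{c,a}(x) = (1 + c x / a)^{-1/c}, \quad x \ge 0.}
#' Only strictly heavy tails (`c > 0`) are admitted: the exponential limit
#' `c = 0` is memoryless under thresholding and carries no information about
#' progressively deeper levels, and `c < 0` implies bounded support, which is
#' incompatible with an unbounded reciprocal resistance.
#'
#' @param c tail index, strictly positive.
#' @param a scale, strictly positive, in units of \eqn{\tilde R}.
#' @return An object of class `"gpd_params"`: a list with elements `c` and `a`.
#' @examples
#' th <- gpd_params(0.8, 1.5)
#' gpd_quantile(1 - 1e-3, th)
#' @export
gpd_params <- function(c, a) {
  stopifnot(is.numeric(c), length(c) == 1L, is.finite(c),
            is.numeric(a), length(a) == 1L, is.finite(a))
  if (c <= 0) stop("tail index 'c' must be strictly positive", call. = FALSE)
  if (a <= 0) stop("scale 'a' must be strictly positive", call. = FALSE)
  structure(list(c = as.numeric(c), a = as.numeric(a)), class = "gpd_params")
}

#' @export
print.gpd_params <- function(x, ...) {
  cat(sprintf("GPD parameters: c = %g (tail index), a = %g (scale)\n", x$c, x$a))
  invisible(x)
}

#' Weibull parameters
#'
#' Scale/shape parameterization of the Weibull model for the reciprocal
#' resistance, with survival function
#' \eqn{\exp\{-(x/\mathrm{scale})^{\mathrm{shape}}\}}.
#'
#' @param scale positive scale parameter.
#' @param shape positive shape parameter.
#' @return An object of class `"weibull_params"`.
#' @export
weibull_params <- function(scale, shape) {
  stopifnot(is.numeric(scale), length(scale) == 1L, is.finite(scale),
            is.numeric(shape), length(shape) == 1L, is.finite(shape))
  if (scale <= 0) stop("'scale' must be strictly positive", call. = FALSE)
  if (shape <= 0) stop("'shape' must be strictly positive", call. = FALSE)
  structure(list(scale = as.numeric(scale), shape = as.numeric(shape)),
            class = "weibull_params")
}

#' @export
print.weibull_params <- function(x, ...) {
  cat(sprintf("Weibull parameters: scale = %g, shape = %g\n", x$scale, x$shape))
  invisible(x)
}

#' GPD survival, distribution and quantile functions
#'
#' `gpd_sf()` evaluates \eqn{(1 + cx/a)^{-1/c}}, `gpd_cdf()` its complement,
#' and `gpd_quantile()` the exact inverse
#' \eqn{q(u) = (a/c)\{(1-u)^{-c} - 1\}}.
#'
#' @param x vector of nonnegative evaluation points.
#' @param u vector of probability levels in `[0, 1)`.
#' @param params a [gpd_params()] object.
#' @return `gpd_sf`/`gpd_cdf`: probabilities; `gpd_quantile`: nonnegative
#'   quantiles on the \eqn{\tilde R} scale.
#' @examples
#' gpd_quantile(1 - 1e-3, gpd_params(0.8, 1.5))  # 469.1037
#' @export
gpd_sf <- function(x, params) {
  stopifnot(inherits(params, "gpd_params"), is.numeric(x))
  if (any(x < 0)) stop("'x' must be nonnegative", call. = FALSE)
  (1 + params$c * x / params$a)^(-1 / params$c)
}

#' @rdname gpd_sf
#' @export
gpd_cdf <- function(x, params) 1 - gpd_sf(x, params)

#' @rdname gpd_sf
#' @export
gpd_quantile <- function(u, params) {
  stopifnot(inherits(params, "gpd_params"), is.numeric(u))
  if (any(u < 0 | u >= 1)) stop("'u' must lie in [0, 1)", call. = FALSE)
  (params$a / params$c) * ((1 - u)^(-params$c) - 1)
}

#' Threshold conditioning of a GPD
#'
#' The excess \eqn{\tilde R - s} given \eqn{\tilde R > s} of a GPD(c, a)
#' variable is again GPD with unchanged tail index and scale `a + c s`.  This
#' stability is what makes the splitting ladder tractable: every stage of the
#' sequential design lives in the same two-parameter family.
#'
#' @param params a [gpd_params()] object for the unconditional law.
#' @param s nonnegative conditioning threshold.
#' @return A [gpd_params()] object for the conditional excess law.
#' @export
gpd_condition <- function(params, s) {
  stopifnot(inherits(params, "gpd_params"), is.numeric(s), length(s) == 1L)
  if (s < 0) stop("threshold 's' must be nonnegative", call. = FALSE)
  gpd_params(params$c, params$a + params$c * s)
}

#' Recover unconditional GPD parameters from a threshold-conditioned estimate
#'
#' Inverse of [gpd_condition()]: an estimate \eqn{(\hat c, \hat a)} of the
#' conditional excess law above `s` maps back to
#' \eqn{(\hat c, \hat a - \hat c s)} for the unconditional law.  A nonpositive
#' recovered scale means the conditional estimate is incompatible with any
#' unconditional GPD at that threshold; the result is returned unclassed with
#' a `valid = FALSE` flag rather than silently clipped.
#'
#' @param params a [gpd_params()] object estimated for the excess law above `s`.
#' @param s nonnegative threshold at which `params` was estimated.
#' @return A [gpd_params()] object, or (when the recovered scale is
#'   nonpositive) a plain list with elements `c`, `a` and `valid = FALSE`.
#' @export
recover_initial <- function(params, s) {
  stopifnot(inherits(params, "gpd_params"), is.numeric(s), length(s) == 1L, s >= 0)
  a0 <- params$a - params$c * s
  if (a0 <= 0) {
    return(list(c = params$c, a = a0, valid = FALSE))
  }
  gpd_params(params$c, a0)
}

#' Weibull survival and quantile functions
#'
#' @param x vector of nonnegative evaluation points.
#' @param u vector of probability levels in `[0, 1)`.
#' @param params a [weibull_params()] object.
#' @examples
#' weibull_quantile(1 - 1e-3, weibull_params(3, 0.9))  # 25.69
#' @export
weibull_sf <- function(x, params) {
  stopifnot(inherits(params, "weibull_params"), is.numeric(x))
  if (any(x < 0)) stop("'x' must be nonnegative", call. = FALSE)
  exp(-(x / params$scale)^params$shape)
}

#' @rdname weibull_sf
#' @export
weibull_quantile <- function(u, params) {
  stopifnot(inherits(params, "weibull_params"), is.numeric(u))
  if (any(u < 0 | u >= 1)) stop("'u' must lie in [0, 1)", call. = FALSE)
  params$scale * (-log(1 - u))^(1 / params$shape)
}

#' Scale-free conditional log-survival identities for the Weibull model
#'
#' For a Weibull with shape \eqn{\beta}, the conditional log survival between
#' two thresholds is determined by the shape and one previously observed
#' conditional probability, without knowledge of the scale:
#' \deqn{\log P(\tilde R > s_2 \mid \tilde R > s_1) =
#'   \{(s_2/s_1)^\beta - 1\}\,\log P(\tilde R > s_1).}
#' `weibull_cond_log_sf()` implements this two-level form.
#' `weibull_cond_log_sf3()` implements the three-level ratio form used deeper
#' in the ladder, where the reference probability is itself conditional:
#' \deqn{\log P(\tilde R > s_{j+1} \mid \tilde R > s_j) =
#'   \left\{\frac{s_{j-1}^\beta - s_{j+1}^\beta}{s_{j-1}^\beta - s_j^\beta} - 1\right\}
#'   \log P(\tilde R > s_j \mid \tilde R > s_{j-1}).}
#' These identities drive both the Weibull threshold updates and the shape
#' estimator.
#'
#' @param s_prev,s_next thresholds with `0 < s_prev <= s_next`.
#' @param s_jm1,s_j,s_jp1 increasing threshold triple (`s_jm1` may be 0, in
#'   which case the three-level form reduces to the two-level one).
#' @param shape Weibull shape parameter.
#' @param log_p_prev (strictly negative) log of the reference survival
#'   probability: unconditional past `s_prev` for the two-level form,
#'   conditional on exceeding `s_jm1` for the three-level form.
#' @return The conditional log survival probability (nonpositive).
#' @export
weibull_cond_log_sf <- function(s_prev, s_next, shape, log_p_prev) {
  stopifnot(is.numeric(s_prev), is.numeric(s_next), is.numeric(shape),
            is.numeric(log_p_prev))
  if (s_prev <= 0) stop("'s_prev' must be strictly positive", call. = FALSE)
  if (any(s_next < s_prev)) stop("'s_next' must be >= 's_prev'", call. = FALSE)
  if (log_p_prev >= 0) stop("'log_p_prev' must be strictly negative", call. = FALSE)
  if (shape <= 0) stop("'shape' must be strictly positive", call. = FALSE)
  ((s_next / s_prev)^shape - 1) * log_p_prev
}

#' @rdname weibull_cond_log_sf
#' @export
weibull_cond_log_sf3 <- function(s_jm1, s_j, s_jp1, shape, log_p_prev) {
  stopifnot(is.numeric(s_jm1), is.numeric(s_j), is.numeric(s_jp1))
  if (s_jm1 < 0 || s_j <= s_jm1 || s_jp1 < s_j)
    stop("thresholds must satisfy 0 <= s_jm1 < s_j <= s_jp1", call. = FALSE)
  if (log_p_prev >= 0) stop("'log_p_prev' must be strictly negative", call. = FALSE)
  if (shape <= 0) stop("'shape' must be strictly positive", call. = FALSE)
  r <- (s_jm1^shape - s_jp1^shape) / (s_jm1^shape - s_j^shape)
  (r - 1) * log_p_prev
}

#' GPD survival via its Gamma-mixture (Laplace transform) representation
#'
#' For `c > 0` the GPD survival function is completely monotone and equals the
#' Laplace transform of a Gamma random variable with shape `1/c` and rate
#' `a/c`:
#' \deqn{\bar F_{c,a}(x) = \int_0^\infty e^{-xy} v(y)\,dy, \qquad
#'   v = \mathrm{Gamma}(\mathrm{shape} = 1/c, \mathrm{rate} = a/c).}
#' This is exposed as a numerical cross-check of the closed form (it is an
#' identity, not an alternative hot path), using adaptive quadrature on
#' \eqn{[0, \infty)}.
#'
#' @param x nonnegative scalar evaluation point.
#' @param params a [gpd_params()] object.
#' @param quad_tol absolute quadrature tolerance (default `1e-9`).
#' @return The mixture integral, equal to `gpd_sf(x, params)` up to
#'   quadrature error.
#' @export
gpd_sf_gamma_mixture <- function(x, params, quad_tol = 1e-9) {
  stopifnot(inherits(params, "gpd_params"), is.numeric(x), length(x) == 1L)
  if (x < 0) stop("'x' must be nonnegative", call. = FALSE)
  shp <- 1 / params$c
  rate <- params$a / params$c
  res <- stats::integrate(function(y) exp(-x * y) * stats::dgamma(y, shape = shp, rate = rate),
                          lower = 0, upper = Inf,
                          abs.tol = quad_tol, rel.tol = quad_tol)
  if (res$message != "OK")
    stop(sprintf("quadrature failed: %s (abs.error = %g)", res$message, res$abs.error),
         call. = FALSE)
  res$value
}

#' Transformed-GPD survival families
#'
#' Flexible deformations of the GPD obtained by composing its distribution
#' function with an increasing bijection \eqn{L} of `[0, 1]`:
#' \eqn{\bar W(x) = 1 - L(G_{c,a}(x))}.  The tail still converges to the GPD
#' tail while the behavior near the origin is reshaped.  Four admissible forms
#' are provided (each with `L(0) = 0`, `L(1) = 1` and a completely monotone
#' complement when composed with a GPD):
#' \describe{
#'   \item{exponential}{\eqn{L(x) = \{1 - e^{-\lambda x^\kappa}\}/(1 - e^{-\lambda})},
#'     with rate `form_param` \eqn{= \lambda > 0} and exponent
#'     \eqn{\kappa \in (0, 1]} (default 1).}
#'   \item{logarithmic}{\eqn{L(x) = \log(x + 1)/\log 2}.}
#'   \item{root}{\eqn{L(x) = (\sqrt{x + 1} - 1)/(\sqrt 2 - 1)}.}
#'   \item{fraction}{\eqn{L(x) = (\kappa + 1)x/(x + \kappa)} with
#'     `form_param` \eqn{= \kappa > 0}.}
#' }
#' These transformations lose the exact threshold-conditioning stability of
#' the plain GPD, so they are not usable as stage models of the sequential
#' design; they describe what the design gives up by committing to the GPD.
#'
#' @param base a [gpd_params()] object for the underlying GPD.
#' @param form one of `"exponential"`, `"logarithmic"`, `"root"`, `"fraction"`.
#' @param form_param positive parameter (rate of the exponential form,
#'   \eqn{\kappa} of the fraction form; ignored otherwise).
#' @param exponent exponent of the exponential form, in `(0, 1]`.
#' @return `transformed_gpd_spec()` returns a `"transformed_gpd_spec"` object;
#'   `transformed_gpd_sf()` returns survival probabilities.
#' @export
transformed_gpd_spec <- function(base,
                                 form = c("exponential", "logarithmic", "root", "fraction"),
                                 form_param = 1, exponent = 1) {
  stopifnot(inherits(base, "gpd_params"))
  form <- match.arg(form)
  if (form %in% c("exponential", "fraction")) {
    stopifnot(is.numeric(form_param), length(form_param) == 1L)
    if (form_param <= 0) stop("'form_param' must be strictly positive", call. = FALSE)
  }
  if (form == "exponential") {
    if (exponent <= 0 || exponent > 1)
      stop("'exponent' must lie in (0, 1]", call. = FALSE)
  }
  structure(list(base = base, form = form, form_param = form_param,
                 exponent = exponent),
            class = "transformed_gpd_spec")
}

#' @rdname transformed_gpd_spec
#' @param x vector of nonnegative evaluation points.
#' @param spec a `"transformed_gpd_spec"` object.
#' @export
transformed_gpd_sf <- function(x, spec) {
  stopifnot(inherits(spec, "transformed_gpd_spec"))
  if (any(x < 0)) stop("'x' must be nonnegative", call. = FALSE)
  g <- gpd_cdf(x, spec$base)
  L <- switch(spec$form,
    exponential = (1 - exp(-spec$form_param * g^spec$exponent)) /
                  (1 - exp(-spec$form_param)),
    logarithmic = log(g + 1) / log(2),
    root        = (sqrt(g + 1) - 1) / (sqrt(2) - 1),
    fraction    = (spec$form_param + 1) * g / (g + spec$form_param)
  )
  1 - L
}

#' Map between reciprocal-scale and original-scale quantiles
#'
#' The design estimates the large (1 - alpha)-quantile of the reciprocal
#' resistance \eqn{\tilde R = 1/R}; the small alpha-quantile of the resistance
#' itself is its reciprocal: \eqn{q_\alpha = 1/\tilde q_{1-\alpha}}.
#'
#' @param q_tilde strictly positive quantile (either scale; the map is an
#'   involution).
#' @return The reciprocal quantile.
#' @export
reciprocal_quantile <- function(q_tilde) {
  stopifnot(is.numeric(q_tilde))
  if (any(q_tilde <= 0)) stop("'q_tilde' must be strictly positive", call. = FALSE)
  1 / q_tilde
}
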