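#' Empirical exceedance probability of a stage
#'
#' @param outcomes nonempty binary (0/1) vector of stage outcomes, 1 meaning
#'   the latent reciprocal resistance exceeded the stage threshold.
#' @return The arithmetic mean of `outcomes`.
#' @export
empirical_p <- function(outcomes) {
  if (length(outcomes) == 0L) stop("'outcomes' must be nonempty", call. = FALSE)
  stopifnot(all(outcomes %in% c(0, 1)))
  mean(outcomes)
}

# Anscombe-type shrinkage for boundary empirical probabilities: 0 and 1 make
# both the Wald interval and the log-based Weibull identities degenerate.
# The raw value is kept in the stage record; this adjusted value feeds the
# estimators.
shrink_boundary <- function(n_succ, K) {
  p <- n_succ / K
  if (p <= 0 || p >= 1) (n_succ + 0.5) / (K + 1) else p
}

#' Wald confidence interval for a stage exceedance probability
#'
#' The (1 - gamma) normal-approximation interval
#' \eqn{\hat p \pm z_{1-\gamma/2}\sqrt{\hat p(1-\hat p)/(K-1)}}
#' (note the `K - 1` denominator), clipped to `[0, 1]`.  It defines the
#' admissible set of stage parameters: candidate GPD parameters are plausible
#' when their implied stage exceedance probability falls inside it.
#'
#' @param p_hat empirical exceedance probability, strictly inside `(0, 1)`
#'   (boundary values are shrunk upstream by the design loop).
#' @param K number of trials in the stage, at least 2.
#' @param gamma complement of the confidence level (the design default
#'   `gamma = 0.2` gives an 80% interval).
#' @return An object of class `"admissible_interval"`: numeric
#'   `c(lower, upper)`.
#' @export
wald_interval <- function(p_hat, K, gamma) {
  stopifnot(is.numeric(p_hat), length(p_hat) == 1L,
            is.numeric(K), length(K) == 1L,
            is.numeric(gamma), length(gamma) == 1L)
  if (K < 2) stop("'K' must be at least 2", call. = FALSE)
  if (p_hat <= 0 || p_hat >= 1)
    stop("'p_hat' must lie strictly inside (0, 1); shrink boundary values first",
         call. = FALSE)
  if (gamma <= 0 || gamma >= 1) stop("'gamma' must lie in (0, 1)", call. = FALSE)
  hw <- stats::qnorm(1 - gamma / 2) * sqrt(p_hat * (1 - p_hat) / (K - 1))
  structure(c(lower = max(0, p_hat - hw), upper = min(1, p_hat + hw)),
            class = "admissible_interval")
}

#' Admissibility of a GPD parameter pair at a stage
#'
#' A candidate pair is admissible when the conditional exceedance probability
#' it implies for the current stage, \eqn{1 - G_{c,a}(s_j - s_{j-1})}, falls
#' inside the stage's confidence interval.  Here `(c, a)` parameterize the
#' conditional excess law above `s_jm1` (condition unconditional candidates
#' with [gpd_condition()] first).
#'
#' @param c,a candidate tail index and scale of the conditional law above
#'   `s_jm1`.
#' @param s_j,s_jm1 current and previous thresholds, `s_j > s_jm1 >= 0`.
#' @param interval a [wald_interval()] (or any numeric `c(lower, upper)`).
#' @return Logical flag (vectorized over `c` and `a`).
#' @export
is_admissible <- function(c, a, s_j, s_jm1, interval) {
  stopifnot(is.numeric(c), is.numeric(a), length(s_j) == 1L, length(s_jm1) == 1L)
  if (s_jm1 < 0 || s_j <= s_jm1)
    stop("thresholds must satisfy s_j > s_jm1 >= 0", call. = FALSE)
  sf <- (1 + c * (s_j - s_jm1) / a)^(-1 / c)
  sf >= interval[[1]] & sf <= interval[[2]]
}

#' Backward-consistency objective for the dual-criterion estimator
#'
#' Measures how well a candidate unconditional GPD pair `(c, a)` reproduces
#' the previously realized threshold increment: the increment
#' \eqn{s_{j-1} - s_{j-2}} should equal the \eqn{(1-\hat p_{j-1})}-quantile of
#' the candidate conditional law above \eqn{s_{j-2}}, i.e. of
#' GPD\eqn{(c, a + c\,s_{j-2})}.  The objective is the absolute discrepancy
#' \deqn{\left|(s_{j-1} - s_{j-2}) -
#'   G^{-1}_{(c,\,a + c s_{j-2})}(1 - \hat p_{j-1})\right|.}
#'
#' @param c,a candidate unconditional tail index and scale (vectorized).
#' @param s_jm1,s_jm2 previous two thresholds, `s_jm1 > s_jm2 >= 0` (the
#'   ladder origin convention is `s_0 = 0`).
#' @param p_hat_jm1 empirical conditional exceedance probability observed at
#'   threshold `s_jm1`, strictly inside `(0, 1)`.
#' @return Nonnegative objective values.
#' @export
backward_objective <- function(c, a, s_jm1, s_jm2, p_hat_jm1) {
  stopifnot(is.numeric(c), is.numeric(a),
            length(s_jm1) == 1L, length(s_jm2) == 1L, length(p_hat_jm1) == 1L)
  if (s_jm2 < 0 || s_jm1 <= s_jm2)
    stop("thresholds must satisfy s_jm1 > s_jm2 >= 0", call. = FALSE)
  if (p_hat_jm1 <= 0 || p_hat_jm1 >= 1)
    stop("'p_hat_jm1' must lie strictly inside (0, 1)", call. = FALSE)
  q <- (a + c * s_jm2) / c * (p_hat_jm1^(-c) - 1)
  abs((s_jm1 - s_jm2) - q)
}

#' Configuration of the grid-based constrained estimator
#'
#' The dual-criterion minimization is carried out by exhaustive search over a
#' log-spaced grid on a parameter box, optionally followed by Nelder-Mead
#' refinement restricted to the admissible set.  The whole procedure is
#' deterministic: replicate variability enters only through the data.
#'
#' @param c_range,a_range length-2 positive, increasing bounds of the GPD
#'   search box (defaults `c` in `[0.05, 5]`, `a` in `[0.05, 20]`).
#' @param scale_range,shape_range analogous bounds for the Weibull model.
#' @param grid_size number of grid points per axis (default 200, minimum 2).
#' @param refine logical; run local Nelder-Mead refinement from the best grid
#'   node, projected to the admissible set (default `TRUE`).
#' @return An object of class `"estimator_config"`.
#' @export
estimator_config <- function(c_range = c(0.05, 5), a_range = c(0.05, 20),
                             scale_range = c(0.05, 20), shape_range = c(0.05, 5),
                             grid_size = 200, refine = TRUE) {
  chk <- function(r, nm) {
    if (!(is.numeric(r) && length(r) == 2L && all(r > 0) && r[1] < r[2]))
      stop(sprintf("'%s' must be two increasing positive numbers", nm), call. = FALSE)
  }
  chk(c_range, "c_range"); chk(a_range, "a_range")
  chk(scale_range, "scale_range"); chk(shape_range, "shape_range")
  if (grid_size < 2) stop("'grid_size' must be at least 2", call. = FALSE)
  structure(list(c_range = c_range, a_range = a_range,
                 scale_range = scale_range, shape_range = shape_range,
                 grid_size = as.integer(grid_size), refine = isTRUE(refine)),
            class = "estimator_config")
}

# Log-spaced search grid over the (c, a) box; returns long vectors cc, aa.
param_grid <- function(cfg) {
  cs <- exp(seq(log(cfg$c_range[1]), log(cfg$c_range[2]), length.out = cfg$grid_size))
  as <- exp(seq(log(cfg$a_range[1]), log(cfg$a_range[2]), length.out = cfg$grid_size))
  list(cc = rep(cs, times = length(as)), aa = rep(as, each = length(cs)))
}

# Deterministic tie-break among equal-objective nodes: smallest c, then
# smallest a (parsimony toward lighter tails).
pick_min <- function(obj, cc, aa) {
  m <- min(obj)
  idx <- which(obj == m)
  if (length(idx) > 1L) idx <- idx[order(cc[idx], aa[idx])][1L]
  idx
}

#' Dual-criterion stage estimator for the GPD model
#'
#' Minimizes the [backward_objective()] over the unconditional parameter box,
#' restricted to candidates admissible at the current stage (their implied
#' conditional exceedance probability at `s_j` lies inside `interval`).  If
#' the admissible set is empty on the grid, the interval is widened once (the
#' caller passes `fallback_interval`, conventionally the interval with gamma
#' halved); if still empty, an error of class `"splitquant_estimation_error"`
#' is thrown.
#'
#' @param s_jm2,s_jm1,s_j increasing threshold triple (`s_jm2` may be 0).
#' @param p_hat_jm1 empirical exceedance probability observed at `s_jm1`
#'   (strictly inside `(0, 1)`).
#' @param interval the stage-`j` [wald_interval()].
#' @param cfg an [estimator_config()].
#' @param fallback_interval optional wider interval used when the admissible
#'   set is empty on the grid.
#' @return A list: `params` ([gpd_params()] on the unconditional scale),
#'   `objective` (attained backward criterion), `widened` (logical).
#' @export
estimate_stage <- function(s_jm2, s_jm1, s_j, p_hat_jm1, interval, cfg,
                           fallback_interval = NULL) {
  stopifnot(inherits(cfg, "estimator_config"))
  if (!(s_jm2 >= 0 && s_jm1 > s_jm2 && s_j > s_jm1))
    stop("thresholds must satisfy s_j > s_jm1 > s_jm2 >= 0", call. = FALSE)
  g <- param_grid(cfg)
  cc <- g$cc; aa <- g$aa
  d <- s_j - s_jm1
  sf_j <- (1 + cc * d / (aa + cc * s_jm1))^(-1 / cc)
  adm <- sf_j >= interval[[1]] & sf_j <= interval[[2]]
  widened <- FALSE
  used <- interval
  if (!any(adm) && !is.null(fallback_interval)) {
    used <- fallback_interval
    adm <- sf_j >= used[[1]] & sf_j <= used[[2]]
    widened <- TRUE
  }
  if (!any(adm)) {
    stop(structure(class = c("splitquant_estimation_error", "error", "condition"),
                   list(message = "empty admissible set after interval widening",
                        call = sys.call())))
  }
  q <- (aa + cc * s_jm2) / cc * (p_hat_jm1^(-cc) - 1)
  obj <- abs((s_jm1 - s_jm2) - q)
  obj[!adm] <- Inf
  idx <- pick_min(obj, cc, aa)
  best <- c(cc[idx], aa[idx]); best_obj <- obj[idx]
  if (cfg$refine) {
    pen <- function(lp) {
      c0 <- exp(lp[1]); a0 <- exp(lp[2])
      if (c0 < cfg$c_range[1] || c0 > cfg$c_range[2] ||
          a0 < cfg$a_range[1] || a0 > cfg$a_range[2]) return(1e12)
      sf <- (1 + c0 * d / (a0 + c0 * s_jm1))^(-1 / c0)
      if (sf < used[[1]] || sf > used[[2]]) return(1e12)
      backward_objective(c0, a0, s_jm1, s_jm2, p_hat_jm1)
    }
    opt <- stats::optim(log(best), pen, method = "Nelder-Mead",
                        control = list(maxit = 200, reltol = 1e-12))
    if (is.finite(opt$value) && opt$value < best_obj && opt$value < 1e11) {
      best <- exp(opt$par); best_obj <- opt$value
    }
  }
  list(params = gpd_params(best[1], best[2]), objective = best_obj,
       widened = widened)
}

#' First-stage GPD estimate under identifiability limits
#'
#' A single stage provides one Bernoulli probability for two parameters, so
#' the admissible set is a whole curve in the box.  Mimicking the reliance on
#' prior judgment at the first level, the estimate is the admissible grid node
#' closest (Euclidean distance after log-scaling both axes) to the geometric
#' center of the search box.
#'
#' @param s1 first threshold (> 0).
#' @param interval stage-1 [wald_interval()].
#' @param cfg an [estimator_config()].
#' @param fallback_interval optional wider interval used when no grid node is
#'   admissible.
#' @return A list with `params`, `objective` (`NA`; no backward criterion at
#'   stage 1) and `widened`.
#' @export
estimate_stage1 <- function(s1, interval, cfg, fallback_interval = NULL) {
  stopifnot(inherits(cfg, "estimator_config"), s1 > 0)
  g <- param_grid(cfg)
  cc <- g$cc; aa <- g$aa
  sf1 <- (1 + cc * s1 / aa)^(-1 / cc)
  adm <- sf1 >= interval[[1]] & sf1 <= interval[[2]]
  widened <- FALSE
  if (!any(adm) && !is.null(fallback_interval)) {
    adm <- sf1 >= fallback_interval[[1]] & sf1 <= fallback_interval[[2]]
    widened <- TRUE
  }
  if (!any(adm)) {
    stop(structure(class = c("splitquant_estimation_error", "error", "condition"),
                   list(message = "empty stage-1 admissible set after interval widening",
                        call = sys.call())))
  }
  lc0 <- mean(log(cfg$c_range)); la0 <- mean(log(cfg$a_range))
  dist2 <- (log(cc) - lc0)^2 + (log(aa) - la0)^2
  dist2[!adm] <- Inf
  idx <- pick_min(dist2, cc, aa)
  list(params = gpd_params(cc[idx], aa[idx]), objective = NA_real_,
       widened = widened)
}

# Weibull analogue of estimate_stage1: admissible (scale, shape) node closest
# to the log-center of the Weibull box.
estimate_stage1_weibull <- function(s1, interval, cfg, fallback_interval = NULL) {
  stopifnot(inherits(cfg, "estimator_config"), s1 > 0)
  sc <- exp(seq(log(cfg$scale_range[1]), log(cfg$scale_range[2]),
                length.out = cfg$grid_size))
  sh <- exp(seq(log(cfg$shape_range[1]), log(cfg$shape_range[2]),
                length.out = cfg$grid_size))
  scg <- rep(sc, times = length(sh)); shg <- rep(sh, each = length(sc))
  sf1 <- exp(-(s1 / scg)^shg)
  adm <- sf1 >= interval[[1]] & sf1 <= interval[[2]]
  widened <- FALSE
  if (!any(adm) && !is.null(fallback_interval)) {
    adm <- sf1 >= fallback_interval[[1]] & sf1 <= fallback_interval[[2]]
    widened <- TRUE
  }
  if (!any(adm)) {
    stop(structure(class = c("splitquant_estimation_error", "error", "condition"),
                   list(message = "empty stage-1 admissible set after interval widening",
                        call = sys.call())))
  }
  ls0 <- mean(log(cfg$scale_range)); lb0 <- mean(log(cfg$shape_range))
  dist2 <- (log(scg) - ls0)^2 + (log(shg) - lb0)^2
  dist2[!adm] <- Inf
  idx <- pick_min(dist2, scg, shg)
  list(params = weibull_params(scg[idx], shg[idx]), objective = NA_real_,
       widened = widened)
}

#' Bernoulli log-likelihood of binary stage outcomes
#'
#' \eqn{\sum_i y_i \log \pi + (1 - y_i)\log(1 - \pi)} for a model exceedance
#' probability `prob`.  A boundary probability mismatched with the data
#' returns `-Inf` (documented sentinel), so separation never produces `NaN`.
#'
#' @param prob model exceedance probability at the stage threshold (scalar).
#' @param outcomes binary outcome vector.
#' @return The log-likelihood (possibly `-Inf`).
#' @export
bernoulli_loglik <- function(prob, outcomes) {
  stopifnot(length(prob) == 1L, all(outcomes %in% c(0, 1)))
  n1 <- sum(outcomes); n0 <- length(outcomes) - n1
  if ((prob <= 0 && n1 > 0) || (prob >= 1 && n0 > 0)) return(-Inf)
  l1 <- if (n1 > 0) n1 * log(prob) else 0
  l0 <- if (n0 > 0) n0 * log(1 - prob) else 0
  l1 + l0
}

#' Naive maximum-likelihood GPD estimate from cumulated stage data
#'
#' The baseline estimator against which the dual criterion is compared: it
#' maximizes the product of stage Bernoulli likelihoods over the same
#' parameter box, unconstrained.  Stage `l` contributes a Bernoulli likelihood
#' with success probability equal to the model conditional exceedance
#' probability \eqn{1 - G_{(c, a + c s_{l-1})}(s_l - s_{l-1})} (with
#' \eqn{s_0 = 0}).  With binary data this surface is notoriously flat along a
#' curve of observationally near-equivalent parameter pairs, which is what
#' drives the baseline's poor extreme-quantile performance.
#'
#' @param thresholds increasing vector of stage thresholds
#'   \eqn{s_1 < \dots < s_j} (the implicit origin is 0).
#' @param n_exceed integer vector of exceedance counts per stage.
#' @param n_trials integer vector of trial counts per stage.
#' @param cfg an [estimator_config()].
#' @return A list with `params` ([gpd_params()], unconditional scale) and
#'   `loglik` (attained log-likelihood).
#' @export
ml_estimate <- function(thresholds, n_exceed, n_trials, cfg) {
  stopifnot(inherits(cfg, "estimator_config"),
            length(thresholds) == length(n_exceed),
            length(thresholds) == length(n_trials))
  if (any(diff(c(0, thresholds)) <= 0))
    stop("'thresholds' must be strictly increasing and positive", call. = FALSE)
  g <- param_grid(cfg)
  cc <- g$cc; aa <- g$aa
  ll <- 0
  prev <- 0
  for (l in seq_along(thresholds)) {
    d <- thresholds[l] - prev
    pil <- (1 + cc * d / (aa + cc * prev))^(-1 / cc)
    ll <- ll + n_exceed[l] * log(pil) + (n_trials[l] - n_exceed[l]) * log1p(-pil)
    prev <- thresholds[l]
  }
  idx <- pick_min(-ll, cc, aa)
  best <- c(cc[idx], aa[idx]); best_ll <- ll[idx]
  if (cfg$refine) {
    nll <- function(lp) {
      c0 <- exp(lp[1]); a0 <- exp(lp[2])
      if (c0 < cfg$c_range[1] || c0 > cfg$c_range[2] ||
          a0 < cfg$a_range[1] || a0 > cfg$a_range[2]) return(1e12)
      tot <- 0; prev <- 0
      for (l in seq_along(thresholds)) {
        d <- thresholds[l] - prev
        pil <- (1 + c0 * d / (a0 + c0 * prev))^(-1 / c0)
        tot <- tot + n_exceed[l] * log(pil) + (n_trials[l] - n_exceed[l]) * log1p(-pil)
        prev <- thresholds[l]
      }
      -tot
    }
    opt <- stats::optim(log(best), nll, method = "Nelder-Mead",
                        control = list(maxit = 200, reltol = 1e-12))
    if (is.finite(opt$value) && -opt$value > best_ll && opt$value < 1e11) {
      best <- exp(opt$par); best_ll <- -opt$value
    }
  }
  list(params = gpd_params(best[1], best[2]), loglik = best_ll)
}

#' Weibull shape estimate from the observed stage history
#'
#' Matches the observed conditional exceedance fractions to the scale-free
#' three-level identity (see [weibull_cond_log_sf3()]): with the ladder origin
#' \eqn{s_0 = 0}, each stage \eqn{j \ge 2} yields a residual
#' \deqn{r_j(\beta) = \log \hat p_j -
#'   \left\{\frac{s_{j-2}^\beta - s_j^\beta}{s_{j-2}^\beta - s_{j-1}^\beta} - 1\right\}
#'   \log \hat p_{j-1}.}
#' With exactly two completed stages the single residual is solved by
#' bracketed root finding on `shape_range` (an error of class
#' `"splitquant_estimation_error"` if the bracket shows no sign change); with
#' more stages the sum of squared residuals is minimized by golden-section
#' search on the same interval.
#'
#' @param thresholds increasing vector of stage thresholds
#'   \eqn{s_1 < \dots < s_J}, `J >= 2`.
#' @param p_hats conditional exceedance fractions per stage (strictly inside
#'   `(0, 1)`; shrink boundary values first).
#' @param shape_range length-2 positive bracket for the shape.
#' @return The estimated shape.
#' @export
weibull_estimate_shape <- function(thresholds, p_hats, shape_range = c(0.05, 5)) {
  J <- length(thresholds)
  stopifnot(J >= 2L, length(p_hats) == J)
  if (any(diff(c(0, thresholds)) <= 0))
    stop("'thresholds' must be strictly increasing and positive", call. = FALSE)
  if (any(p_hats <= 0 | p_hats >= 1))
    stop("'p_hats' must lie strictly inside (0, 1)", call. = FALSE)
  t_full <- c(0, thresholds)
  lp <- log(p_hats)
  resid <- function(beta) {
    vapply(2:J, function(j) {
      sm2 <- t_full[j - 1]; sm1 <- t_full[j]; sj <- t_full[j + 1]
      r <- (sm2^beta - sj^beta) / (sm2^beta - sm1^beta)
      lp[j] - (r - 1) * lp[j - 1]
    }, numeric(1))
  }
  if (J == 2L) {
    f <- function(beta) resid(beta)[1]
    lo <- f(shape_range[1]); hi <- f(shape_range[2])
    if (!is.finite(lo) || !is.finite(hi) || lo * hi > 0) {
      stop(structure(class = c("splitquant_estimation_error", "error", "condition"),
                     list(message = "no sign change in the shape bracket",
                          call = sys.call())))
    }
    stats::uniroot(f, interval = shape_range, tol = 1e-10)$root
  } else {
    ss <- function(beta) sum(resid(beta)^2)
    stats::optimize(ss, interval = shape_range, tol = 1e-10)$minimum
  }
}
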