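#' Conservative number of splitting stages
#'
#' The smallest number of stages whose per-stage conditional level `p`
#' reaches the target risk: \eqn{m = \lceil \log\alpha / \log p \rceil},
#' so that \eqn{p^m \le \alpha}.
#'
#' @param alpha target risk level in `(0, p)`.
#' @param p per-stage conditional exceedance level in `(alpha, 1)`.
#' @return Integer stage count.
#' @examples
#' conservative_stage_count(1e-3, 0.25)  # 5
#' @export
conservative_stage_count <- function(alpha, p) {
  stopifnot(is.numeric(alpha), is.numeric(p), length(alpha) == 1L, length(p) == 1L)
  if (!(alpha > 0 && alpha <= p && p < 1))
    stop("must have 0 < alpha <= p < 1", call. = FALSE)
  as.integer(ceiling(log(alpha) / log(p)))
}

#' Configuration of one sequential splitting design
#'
#' Everything needed to run one design: target risk `alpha`, per-stage
#' conditional level `p`, stage count `m`, trials per stage `K`, confidence
#' complement `gamma` of the admissible interval, the first threshold on the
#' reciprocal scale, the tail-model family, the estimator search box, and the
#' root seed.
#'
#' @param alpha target risk level (default `1e-3`).
#' @param p per-stage conditional exceedance level (default `0.25`).
#' @param m number of stages; default [conservative_stage_count()]`(alpha, p)`.
#' @param K trials per stage (default 50).
#' @param gamma complement of the confidence level of the stage interval
#'   (default 0.2, i.e. 80% intervals).
#' @param s1_tilde first threshold on the reciprocal-resistance scale (> 0).
#' @param model `"gpd"` or `"weibull"`.
#' @param estimator_cfg an [estimator_config()].
#' @param seed root RNG seed; all per-stage streams are derived from it.
#' @return An object of class `"design_config"`.
#' @export
design_config <- function(alpha = 1e-3, p = 0.25,
                          m = conservative_stage_count(alpha, p),
                          K = 50, gamma = 0.2, s1_tilde,
                          model = c("gpd", "weibull"),
                          estimator_cfg = estimator_config(),
                          seed = 1L) {
  model <- match.arg(model)
  stopifnot(is.numeric(s1_tilde), length(s1_tilde) == 1L)
  if (!(alpha > 0 && alpha < p && p < 1))
    stop("must have 0 < alpha < p < 1", call. = FALSE)
  if (m < 2) stop("'m' must be at least 2", call. = FALSE)
  if (K < 1) stop("'K' must be at least 1", call. = FALSE)
  if (gamma <= 0 || gamma >= 1) stop("'gamma' must lie in (0, 1)", call. = FALSE)
  if (s1_tilde <= 0) stop("'s1_tilde' must be strictly positive", call. = FALSE)
  stopifnot(inherits(estimator_cfg, "estimator_config"))
  structure(list(alpha = alpha, p = p, m = as.integer(m), K = as.integer(K),
                 gamma = gamma, s1_tilde = s1_tilde, model = model,
                 estimator_cfg = estimator_cfg, seed = as.integer(seed)),
            class = "design_config")
}

#' Next splitting threshold under an estimated GPD conditional law
#'
#' The next stage level is the `(1 - p)`-quantile of the estimated conditional
#' distribution above the current threshold:
#' `s_prev + gpd_quantile(1 - p, cond_params)`, where `cond_params`
#' parameterize the excess law above `s_prev` (already threshold-adjusted; see
#' [gpd_condition()]).
#'
#' @param cond_params [gpd_params()] of the conditional excess law above
#'   `s_prev`.
#' @param s_prev current threshold (>= 0).
#' @param p per-stage conditional exceedance level in `(0, 1)`.
#' @return The next threshold, strictly greater than `s_prev`.
#' @export
next_threshold <- function(cond_params, s_prev, p) {
  stopifnot(inherits(cond_params, "gpd_params"), s_prev >= 0)
  if (p <= 0 || p >= 1) stop("'p' must lie in (0, 1)", call. = FALSE)
  s_prev + gpd_quantile(1 - p, cond_params)
}

#' Next splitting threshold under the Weibull model
#'
#' Inverts the scale-free three-level identity (see
#' [weibull_cond_log_sf3()]): given the last two thresholds, the shape
#' estimate, and the observed conditional exceedance fraction at `s_prev`,
#' the level whose conditional exceedance probability above `s_prev` is `p`
#' solves
#' \deqn{s_{\mathrm{next}} = \left\{ s_{pp}^\beta -
#'   \Bigl(1 + \tfrac{\log p}{\log \hat p_{\mathrm{prev}}}\Bigr)
#'   (s_{pp}^\beta - s_{\mathrm{prev}}^\beta) \right\}^{1/\beta},}
#' with \eqn{s_{pp}} the threshold before `s_prev` (0 at the ladder origin).
#'
#' @param s_prevprev,s_prev the two most recent thresholds,
#'   `0 <= s_prevprev < s_prev`.
#' @param shape current Weibull shape estimate.
#' @param p target conditional exceedance level.
#' @param p_hat_prev observed conditional exceedance fraction at `s_prev`,
#'   strictly inside `(0, 1)` (boundary values are degenerate for the log
#'   identity).
#' @return The next threshold, strictly greater than `s_prev`.
#' @export
weibull_next_threshold <- function(s_prevprev, s_prev, shape, p, p_hat_prev) {
  stopifnot(is.numeric(s_prevprev), is.numeric(s_prev))
  if (!(s_prevprev >= 0 && s_prev > s_prevprev))
    stop("thresholds must satisfy 0 <= s_prevprev < s_prev", call. = FALSE)
  if (p <= 0 || p >= 1) stop("'p' must lie in (0, 1)", call. = FALSE)
  if (p_hat_prev <= 0 || p_hat_prev >= 1)
    stop("degenerate stage data: 'p_hat_prev' must lie strictly inside (0, 1)",
         call. = FALSE)
  if (shape <= 0) stop("'shape' must be strictly positive", call. = FALSE)
  rad <- s_prevprev^shape -
    (1 + log(p) / log(p_hat_prev)) * (s_prevprev^shape - s_prev^shape)
  if (rad <= s_prev^shape)
    stop("infeasible geometry: next threshold would not exceed 's_prev'",
         call. = FALSE)
  rad^(1 / shape)
}

#' Attained risk level of a completed ladder
#'
#' The product \eqn{\tilde\alpha = \hat p_1 \cdot p^{m-1}} of the realized
#' first-stage exceedance fraction with the per-stage target applied at the
#' remaining `m - 1` stages; the proxy of the target `alpha` actually reached
#' by the ladder.
#'
#' @param p_hat_1 realized first-stage exceedance probability in `(0, 1]`.
#' @param p per-stage conditional level in `(0, 1]`.
#' @param m number of stages (>= 1).
#' @return The attained risk level.
#' @export
attained_alpha <- function(p_hat_1, p, m) {
  stopifnot(p_hat_1 > 0, p_hat_1 <= 1, p > 0, p <= 1, m >= 1)
  p_hat_1 * p^(m - 1)
}

#' Simulate one stage of binary exceedance outcomes
#'
#' Draws `K` i.i.d. Bernoulli outcomes with success probability
#' \eqn{P(\tilde R > s_{\mathrm{cur}} \mid \tilde R > s_{\mathrm{prev}})}
#' computed in closed form under the true model.  This is the synthetic
#' counterpart of testing `K` specimens whose resistance follows the
#' truncated law: only the exceedance indicators are returned, never the
#' latent draws.
#'
#' @param true_params [gpd_params()] or [weibull_params()] of the
#'   unconditional law of \eqn{\tilde R}.
#' @param s_cur,s_prev current and previous thresholds,
#'   `s_cur >= s_prev >= 0`.
#' @param K number of trials.
#' @param seed integer seed for this stage's stream (derive it from the root
#'   seed with [derive_seed()]).
#' @return Integer 0/1 vector of length `K`.
#' @export
sample_stage <- function(true_params, s_cur, s_prev, K, seed) {
  if (!(s_prev >= 0 && s_cur >= s_prev))
    stop("thresholds must satisfy s_cur >= s_prev >= 0", call. = FALSE)
  prob <- true_conditional_sf(true_params, s_cur, s_prev)
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  as.integer(stats::runif(K) < prob)
}

# Closed-form conditional exceedance probability P(R~ > s_cur | R~ > s_prev)
# under the unconditional true law.
true_conditional_sf <- function(true_params, s_cur, s_prev) {
  if (inherits(true_params, "gpd_params")) {
    if (s_prev == 0) return(gpd_sf(s_cur, true_params))
    gpd_sf(s_cur - s_prev, gpd_condition(true_params, s_prev))
  } else if (inherits(true_params, "weibull_params")) {
    weibull_sf(s_cur, true_params) / weibull_sf(s_prev, true_params)
  } else {
    stop("'true_params' must be gpd_params or weibull_params", call. = FALSE)
  }
}

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Run one sequential splitting design
#'
#' Executes the full design: first-stage sampling at `config$s1_tilde` and
#' initial parameter estimation; adjustment of the working conditional level
#' so that \eqn{\hat p_1 \, p_{\mathrm{adj}}^{m-1} = \alpha}; then, for each
#' stage `j = 2, ..., m`, computation of the next threshold from the current
#' estimate, sampling of `K` binary outcomes under the true conditional law,
#' and re-estimation.  The final threshold \eqn{\tilde s_m} estimates the
#' \eqn{(1-\alpha)}-quantile of \eqn{\tilde R}; its reciprocal estimates the
#' \eqn{\alpha}-quantile of the resistance itself.
#'
#' The true parameters drive the simulator only; no estimator ever reads them.
#'
#' @param config a [design_config()].
#' @param true_params [gpd_params()] or [weibull_params()] of the true law
#'   (must match `config$model`).
#' @param estimator `"dual"` for the constrained backward-consistency
#'   estimator, `"ml"` for the naive Bernoulli maximum-likelihood baseline
#'   (GPD only).
#' @param oracle logical; if `TRUE`, estimates are replaced by the true
#'   parameters and empirical fractions by exact conditional probabilities
#'   (a noise-free self-consistency mode used to validate the ladder
#'   telescoping).
#' @return An object of class `"splitting_result"`: a list with the threshold
#'   `ladder`, `q_tilde_est` (final threshold, reciprocal scale), `q_est`
#'   (its reciprocal, original scale), `alpha_attained`, `p_used` (adjusted
#'   per-stage level), per-stage records in `stages`, and
#'   `initial_params_est` (final unconditional-scale parameter estimate).
#' @export
run_splitting <- function(config, true_params, estimator = c("dual", "ml"),
                          oracle = FALSE) {
  stopifnot(inherits(config, "design_config"))
  estimator <- match.arg(estimator)
  if (config$model == "gpd" && !inherits(true_params, "gpd_params"))
    stop("'true_params' must be gpd_params for the GPD model", call. = FALSE)
  if (config$model == "weibull") {
    if (!inherits(true_params, "weibull_params"))
      stop("'true_params' must be weibull_params for the Weibull model", call. = FALSE)
    if (estimator == "ml")
      stop("the ML baseline is implemented for the GPD model only", call. = FALSE)
  }
  if (config$model == "gpd") {
    run_splitting_gpd(config, true_params, estimator, oracle)
  } else {
    run_splitting_weibull(config, true_params, oracle)
  }
}

run_splitting_gpd <- function(config, true_params, estimator, oracle) {
  m <- config$m; K <- config$K; cfg <- config$estimator_cfg
  s <- numeric(m); s[1] <- config$s1_tilde
  stages <- vector("list", m)
  counts_exceed <- integer(m)

  stage_sample <- function(j, s_cur, s_prev) {
    if (oracle) {
      p_exact <- true_conditional_sf(true_params, s_cur, s_prev)
      list(outcomes = NULL, p_raw = p_exact, p_use = p_exact,
           n_exceed = round(p_exact * K))
    } else {
      y <- sample_stage(true_params, s_cur, s_prev, K,
                        derive_seed(config$seed, j))
      n1 <- sum(y)
      list(outcomes = y, p_raw = n1 / K, p_use = shrink_boundary(n1, K),
           n_exceed = n1)
    }
  }
  intervals <- function(p_use) {
    list(main = wald_interval(p_use, K, config$gamma),
         fallback = wald_interval(p_use, K, config$gamma / 2))
  }

  s1d <- stage_sample(1L, s[1], 0)
  counts_exceed[1] <- s1d$n_exceed
  iv1 <- intervals(s1d$p_use)
  est <- if (oracle) {
    list(params = true_params, objective = 0, widened = FALSE)
  } else if (estimator == "ml") {
    fit <- ml_estimate(s[1], s1d$n_exceed, K, cfg)
    list(params = fit$params, objective = -fit$loglik, widened = FALSE)
  } else {
    estimate_stage1(s[1], iv1$main, cfg, iv1$fallback)
  }
  stages[[1]] <- stage_record(1L, s[1], s1d, iv1$main, est)

  # Working per-stage level: solve p_hat_1 * p_adj^(m-1) = alpha, clipped so
  # the ladder stays usable even under an extreme first-stage draw.
  p_use <- clip((config$alpha / s1d$p_use)^(1 / (m - 1)), 0.01, 0.99)

  p_hat_prev <- s1d$p_use
  for (j in 2:m) {
    cond <- gpd_condition(est$params, s[j - 1])
    s[j] <- next_threshold(cond, s[j - 1], p_use)
    sjd <- stage_sample(j, s[j], s[j - 1])
    counts_exceed[j] <- sjd$n_exceed
    ivj <- intervals(sjd$p_use)
    est <- if (oracle) {
      list(params = true_params, objective = 0, widened = FALSE)
    } else if (estimator == "ml") {
      fit <- ml_estimate(s[1:j], counts_exceed[1:j], rep(K, j), cfg)
      list(params = fit$params, objective = -fit$loglik, widened = FALSE)
    } else {
      estimate_stage(s_jm2 = if (j == 2) 0 else s[j - 2],
                     s_jm1 = s[j - 1], s_j = s[j],
                     p_hat_jm1 = p_hat_prev,
                     interval = ivj$main, cfg = cfg,
                     fallback_interval = ivj$fallback)
    }
    stages[[j]] <- stage_record(j, s[j], sjd, ivj$main, est)
    p_hat_prev <- sjd$p_use
  }

  structure(list(model = "gpd",
                 estimator = if (oracle) "oracle" else estimator,
                 ladder = s,
                 q_tilde_est = s[m],
                 q_est = 1 / s[m],
                 alpha_attained = attained_alpha(s1d$p_use, p_use, m),
                 p_used = p_use,
                 stages = stages,
                 initial_params_est = est$params,
                 config = config),
            class = "splitting_result")
}

run_splitting_weibull <- function(config, true_params, oracle) {
  m <- config$m; K <- config$K; cfg <- config$estimator_cfg
  s <- numeric(m); s[1] <- config$s1_tilde
  stages <- vector("list", m)
  p_hats <- numeric(m)

  stage_sample <- function(j, s_cur, s_prev) {
    if (oracle) {
      p_exact <- true_conditional_sf(true_params, s_cur, s_prev)
      list(outcomes = NULL, p_raw = p_exact, p_use = p_exact,
           n_exceed = round(p_exact * K))
    } else {
      y <- sample_stage(true_params, s_cur, s_prev, K,
                        derive_seed(config$seed, j))
      n1 <- sum(y)
      list(outcomes = y, p_raw = n1 / K, p_use = shrink_boundary(n1, K),
           n_exceed = n1)
    }
  }

  s1d <- stage_sample(1L, s[1], 0)
  p_hats[1] <- s1d$p_use
  iv1 <- list(main = wald_interval(s1d$p_use, K, config$gamma),
              fallback = wald_interval(s1d$p_use, K, config$gamma / 2))
  est <- if (oracle) {
    list(params = true_params, objective = 0, widened = FALSE)
  } else {
    estimate_stage1_weibull(s[1], iv1$main, cfg, iv1$fallback)
  }
  shape_hat <- est$params$shape
  stages[[1]] <- stage_record(1L, s[1], s1d, iv1$main, est)

  p_use <- clip((config$alpha / s1d$p_use)^(1 / (m - 1)), 0.01, 0.99)

  for (j in 2:m) {
    s[j] <- if (j == 2) {
      # two-level identity inverted at the ladder origin
      s[1] * (1 + log(p_use) / log(p_hats[1]))^(1 / shape_hat)
    } else {
      weibull_next_threshold(s[j - 2], s[j - 1], shape_hat, p_use, p_hats[j - 1])
    }
    sjd <- stage_sample(j, s[j], s[j - 1])
    p_hats[j] <- sjd$p_use
    ivj <- list(main = wald_interval(sjd$p_use, K, config$gamma),
                fallback = wald_interval(sjd$p_use, K, config$gamma / 2))
    if (oracle) {
      est <- list(params = true_params, objective = 0, widened = FALSE)
      shape_hat <- true_params$shape
    } else {
      shape_hat <- weibull_estimate_shape(s[1:j], p_hats[1:j], cfg$shape_range)
      scale_hat <- s[1] / (-log(p_hats[1]))^(1 / shape_hat)
      est <- list(params = weibull_params(scale_hat, shape_hat),
                  objective = NA_real_, widened = FALSE)
    }
    stages[[j]] <- stage_record(j, s[j], sjd, ivj$main, est)
  }

  structure(list(model = "weibull",
                 estimator = if (oracle) "oracle" else "dual",
                 ladder = s,
                 q_tilde_est = s[m],
                 q_est = 1 / s[m],
                 alpha_attained = attained_alpha(s1d$p_use, p_use, m),
                 p_used = p_use,
                 stages = stages,
                 initial_params_est = est$params,
                 config = config),
            class = "splitting_result")
}

# One per-stage audit record.
stage_record <- function(j, threshold, sampled, interval, est) {
  prm <- est$params
  list(stage = j,
       threshold = threshold,
       outcomes = sampled$outcomes,
       n_exceed = sampled$n_exceed,
       p_hat = sampled$p_raw,
       p_hat_shrunk = sampled$p_use,
       interval = as.numeric(interval),
       est_params = prm,
       objective = est$objective,
       widened = est$widened)
}

#' @export
print.splitting_result <- function(x, ...) {
  cat(sprintf("Sequential splitting design (%s model, %s estimator)\n",
              x$model, x$estimator))
  cat(sprintf("  stages: %d, trials per stage: %d\n",
              length(x$ladder), x$config$K))
  cat("  threshold ladder (reciprocal scale):\n    ",
      paste(signif(x$ladder, 6), collapse = " < "), "\n")
  cat(sprintf("  (1-alpha)-quantile estimate (reciprocal scale): %g\n", x$q_tilde_est))
  cat(sprintf("  alpha-quantile estimate (original scale):       %g\n", x$q_est))
  cat(sprintf("  attained risk level: %g (working p = %g)\n",
              x$alpha_attained, x$p_used))
  invisible(x)
}
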