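#' Configuration of a Dixon-Mood staircase (up-and-down) run
#'
#' @param s_ini initial test level.
#' @param delta fixed level increment (> 0).
#' @param K number of sequential trials (>= 2).
#' @param model latent resistance model: `"exponential"` (rate `par[1]`) or
#'   `"gaussian"` (mean `par[1]`, sd `par[2]`).
#' @param par numeric parameter vector of the latent model.
#' @return An object of class `"staircase_config"`.
#' @export
staircase_config <- function(s_ini, delta, K, model = c("exponential", "gaussian"),
                             par) {
  model <- match.arg(model)
  if (delta <= 0) stop("'delta' must be strictly positive", call. = FALSE)
  if (K < 2) stop("'K' must be at least 2", call. = FALSE)
  if (model == "exponential") {
    stopifnot(length(par) == 1L, par > 0)
  } else {
    stopifnot(length(par) == 2L, par[2] > 0)
  }
  structure(list(s_ini = s_ini, delta = delta, K = as.integer(K),
                 model = model, par = par),
            class = "staircase_config")
}

# Latent failure probability P(R <= s) of the staircase models.
staircase_phi <- function(s, model, par) {
  switch(model,
         exponential = ifelse(s <= 0, 0, 1 - exp(-par[1] * s)),
         gaussian    = stats::pnorm((s - par[1]) / par[2]))
}

#' Simulate a staircase run
#'
#' Sequential up-and-down sampling: each specimen is tested at the current
#' level; the level moves up by `delta` after a survival (latent resistance
#' above the level) and down by `delta` after a failure.  The walk is
#' unconstrained: under a nonnegative latent model a nonpositive level is a
#' trivial trial (the specimen survives with certainty), after which the walk
#' reflects upward; an optional `floor_at` clamps the walk from below for
#' settings where nonpositive test levels must not occur.
#'
#' @param cfg a [staircase_config()].
#' @param seed integer RNG seed.
#' @param floor_at optional lower clamp for the level walk (default none).
#' @return A list with numeric `levels` and integer 0/1 `outcomes`
#'   (1 = failure, i.e. latent resistance at or below the level), each of
#'   length `K`.
#' @export
staircase_run <- function(cfg, seed, floor_at = NULL) {
  stopifnot(inherits(cfg, "staircase_config"))
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  floor_lvl <- if (is.null(floor_at)) -Inf else floor_at
  levels <- numeric(cfg$K)
  outcomes <- integer(cfg$K)
  s <- cfg$s_ini
  u <- stats::runif(cfg$K)
  for (i in seq_len(cfg$K)) {
    levels[i] <- s
    fail <- u[i] < staircase_phi(s, cfg$model, cfg$par)
    outcomes[i] <- as.integer(fail)
    s <- if (fail) max(s - cfg$delta, floor_lvl) else s + cfg$delta
  }
  list(levels = levels, outcomes = outcomes)
}

#' Maximum-likelihood fit of the latent model from staircase data
#'
#' Maximizes the Bernoulli likelihood
#' \eqn{\sum_i y_i \log\phi(s_i,\theta) + (1-y_i)\log\{1-\phi(s_i,\theta)\}}
#' with \eqn{\phi} the latent failure CDF (exponential:
#' \eqn{1 - e^{-\lambda s}}; Gaussian: \eqn{\Phi((s-\mu)/\sigma)}), and reports
#' the implied extreme failure quantile.  Complete separation (no failures or
#' no survivals) throws an error of class `"splitquant_estimation_error"`.
#' The Gaussian fit is a box-constrained probit likelihood with
#' \eqn{\sigma \in [10^{-3}, 10^{3}]}; the exponential rate is searched on
#' \eqn{[10^{-6}, 10^{3}]}.
#'
#' @param levels,outcomes vectors from [staircase_run()].
#' @param model `"exponential"` or `"gaussian"`.
#' @param alpha probability level of the reported failure quantile
#'   (default `1e-3`).
#' @return A list with `par` (named estimates) and `quantile` (the implied
#'   `alpha`-level failure quantile).
#' @export
staircase_mle <- function(levels, outcomes, model = c("exponential", "gaussian"),
                          alpha = 1e-3) {
  model <- match.arg(model)
  stopifnot(length(levels) == length(outcomes), all(outcomes %in% c(0, 1)))
  if (sum(outcomes) == 0L || sum(outcomes) == length(outcomes)) {
    stop(structure(class = c("splitquant_estimation_error", "error", "condition"),
                   list(message = "complete separation: need at least one failure and one survival",
                        call = sys.call())))
  }
  nll <- function(phi) {
    phi <- clip(phi, 1e-12, 1 - 1e-12)
    -sum(outcomes * log(phi) + (1 - outcomes) * log1p(-phi))
  }
  if (model == "exponential") {
    f <- function(loglam) nll(staircase_phi(levels, "exponential", exp(loglam)))
    opt <- stats::optimize(f, interval = log(c(1e-6, 1e3)), tol = 1e-10)
    lam <- exp(opt$minimum)
    list(par = c(rate = lam), quantile = -log(1 - alpha) / lam)
  } else {
    f <- function(th) nll(staircase_phi(levels, "gaussian", c(th[1], exp(th[2]))))
    init <- c(mean(levels), log(max(stats::sd(levels), 1e-2)))
    opt <- stats::optim(init, f, method = "L-BFGS-B",
                        lower = c(-Inf, log(1e-3)), upper = c(Inf, log(1e3)))
    mu <- opt$par[1]; sg <- exp(opt$par[2])
    list(par = c(mean = mu, sd = sg),
         quantile = mu + sg * stats::qnorm(alpha))
  }
}

#' Configuration of a CRM (continual reassessment method) run
#'
#' Bayesian sequential level selection under the exponential latent model.
#' The failure probability at a level carries a Beta prior
#' \eqn{\pi_s \sim \mathrm{Beta}(k, n - k + 1)} ("expect `k` failures out of
#' `n` trials"); after each batch the posterior pseudo-counts are updated and
#' the next tested level is the grid level whose model failure probability is
#' closest to the target.
#'
#' @param levels strictly increasing vector of candidate test levels.
#' @param prior_k,prior_n Beta prior pseudo-counts, `0 < prior_k < prior_n`
#'   (default 2 failures out of 10).
#' @param L Monte-Carlo draws used to average the implied exponential rate
#'   (default 1000).
#' @param J_per_iter trials per iteration.
#' @param N_iter number of iterations.
#' @param alpha_target quantile level targeted by the level selection.
#' @return An object of class `"crm_config"`.
#' @export
crm_config <- function(levels, prior_k = 2, prior_n = 10, L = 1000,
                       J_per_iter = 50, N_iter = 10, alpha_target = 1e-3) {
  stopifnot(length(levels) >= 1L, all(levels > 0), !is.unsorted(levels, strictly = TRUE))
  if (!(prior_k > 0 && prior_k < prior_n))
    stop("must have 0 < prior_k < prior_n", call. = FALSE)
  structure(list(levels = levels, prior_k = prior_k, prior_n = prior_n,
                 L = as.integer(L), J_per_iter = as.integer(J_per_iter),
                 N_iter = as.integer(N_iter), alpha_target = alpha_target),
            class = "crm_config")
}

#' Exponential rate implied by a failure probability at a level
#'
#' Under the exponential model \eqn{P(R \le s) = 1 - e^{-\lambda s}}, a
#' failure probability `pi_s` at level `s` pins down the rate
#' \eqn{\Lambda_s = -\log(1 - \pi_s)/s}.
#'
#' @param pi_s failure probability strictly inside `(0, 1)` (vectorized).
#' @param s positive level.
#' @return Implied rate(s).
#' @export
crm_lambda_draw <- function(pi_s, s) {
  stopifnot(is.numeric(pi_s), length(s) == 1L, s > 0)
  if (any(pi_s <= 0 | pi_s >= 1))
    stop("'pi_s' must lie strictly inside (0, 1)", call. = FALSE)
  -log(1 - pi_s) / s
}

#' Beta posterior pseudo-counts of the CRM
#'
#' Conjugate update of the Beta(k, n - k + 1) prior with cumulative binary
#' data: after `cum_failures` failures in `cum_trials` trials the posterior is
#' \eqn{\mathrm{Beta}\bigl(k + f,\; n + T - (k + f) + 1\bigr)} with
#' \eqn{f} the cumulative failures and \eqn{T} the cumulative trials.
#'
#' @param prior_k,prior_n prior pseudo-counts.
#' @param cum_failures,cum_trials cumulative failure and trial counts
#'   (`cum_failures <= cum_trials`).
#' @return Named numeric `c(shape1, shape2)`.
#' @export
crm_posterior <- function(prior_k, prior_n, cum_failures, cum_trials) {
  stopifnot(cum_failures >= 0, cum_trials >= cum_failures)
  k_post <- prior_k + cum_failures
  c(shape1 = k_post, shape2 = prior_n + cum_trials - k_post + 1)
}

#' Grid level selected by the CRM
#'
#' The level minimizing \eqn{|1 - e^{-\bar\Lambda s_j} - \alpha|}; ties go to
#' the smaller level.
#'
#' @param lambda_bar current rate estimate.
#' @param levels candidate levels.
#' @param alpha_target target failure probability.
#' @return The selected level.
#' @export
crm_select_level <- function(lambda_bar, levels, alpha_target) {
  stopifnot(length(levels) >= 1L)
  d <- abs(1 - exp(-lambda_bar * levels) - alpha_target)
  levels[which.min(d)]  # which.min returns the first (smallest-level) minimum
}

#' Run the continual reassessment method
#'
#' Iterates `N_iter` times: average the implied rate over `L` Monte-Carlo
#' draws from the current Beta law (evaluated at the current level), select
#' the grid level targeting `alpha_target`, run `J_per_iter` Bernoulli trials
#' at it under the true exponential model, update the posterior pseudo-counts.
#' The rate draws start at the middle grid level before any level has been
#' selected.
#'
#' @param cfg a [crm_config()].
#' @param true_rate rate of the true exponential resistance model.
#' @param seed integer RNG seed.
#' @return A list with `q_alpha_est` (last selected level), `lambda_bar`
#'   (final rate estimate), `q10_est` (implied 0.1-quantile
#'   \eqn{-\log 0.9/\bar\Lambda}), and the `trace` of selected levels and
#'   failure counts.
#' @export
crm_run <- function(cfg, true_rate, seed) {
  stopifnot(inherits(cfg, "crm_config"), true_rate > 0)
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  post <- c(shape1 = cfg$prior_k, shape2 = cfg$prior_n - cfg$prior_k + 1)
  cum_f <- 0L; cum_t <- 0L
  s_cur <- cfg$levels[ceiling(length(cfg$levels) / 2)]
  sel <- numeric(cfg$N_iter); fails <- integer(cfg$N_iter)
  lambda_bar <- NA_real_
  for (i in seq_len(cfg$N_iter)) {
    pis <- stats::rbeta(cfg$L, post[["shape1"]], post[["shape2"]])
    pis <- clip(pis, 1e-12, 1 - 1e-12)
    lambda_bar <- mean(crm_lambda_draw(pis, s_cur))
    s_cur <- crm_select_level(lambda_bar, cfg$levels, cfg$alpha_target)
    y <- as.integer(stats::runif(cfg$J_per_iter) < (1 - exp(-true_rate * s_cur)))
    sel[i] <- s_cur; fails[i] <- sum(y)
    cum_f <- cum_f + sum(y); cum_t <- cum_t + cfg$J_per_iter
    post <- crm_posterior(cfg$prior_k, cfg$prior_n, cum_f, cum_t)
  }
  list(q_alpha_est = sel[cfg$N_iter],
       lambda_bar = lambda_bar,
       q10_est = -log(1 - 0.1) / lambda_bar,
       trace = list(levels = sel, failures = fails,
                    posterior = post, cum_trials = cum_t))
}

#' Harmonic tail sum
#'
#' \eqn{\vartheta_{k,n} = \sum_{j=k}^{n} 1/j}, the expected log-spacing sums
#' entering de Valk's extrapolation.
#'
#' @param k,n integer bounds with `1 <= k <= n`.
#' @return The harmonic tail sum.
#' @export
devalk_theta_sum <- function(k, n) {
  stopifnot(length(k) == 1L, length(n) == 1L)
  if (!(k >= 1 && k <= n)) stop("must have 1 <= k <= n", call. = FALSE)
  sum(1 / seq.int(k, n))
}

#' Hill estimator of the tail index
#'
#' Mean log-excess of the top `l` order statistics over the `(n-l)`-th:
#' \eqn{\hat c = \frac{1}{l}\sum_{i=1}^{l} \log X_{n-i+1:n} - \log X_{n-l:n}}.
#'
#' @param sample positive sample vector.
#' @param l number of upper order statistics used.
#' @return The tail index estimate.
#' @export
hill_estimate <- function(sample, l) {
  n <- length(sample)
  stopifnot(l >= 1, l < n, all(sample > 0))
  xs <- sort(sample)
  mean(log(xs[(n - l + 1):n])) - log(xs[n - l])
}

#' Regularity-function level for log-Weibull-type tails
#'
#' For a Weibull-type tail the log quantile function is slowly varying:
#' \eqn{\log q(y) = \log\alpha + (1/\beta)\log y}, so the regularity
#' function of the extrapolation is the constant \eqn{g \equiv 1/\beta}.
#' It is estimated by the least-squares slope of the top `l + 1` log order
#' statistics on the log harmonic sums \eqn{\log\vartheta_{i,n}} (their
#' expected exponential plotting positions); the estimator is exact for the
#' ideal quantile function.
#'
#' @param sample positive sample vector.
#' @param l number of upper order statistics used.
#' @return Estimate of the constant regularity level \eqn{1/\beta}.
#' @export
devalk_g0_estimate <- function(sample, l) {
  n <- length(sample)
  stopifnot(l >= 2, l < n, all(sample > 0))
  xs <- sort(sample)
  idx <- seq_len(l + 1L)
  lx <- log(xs[n - idx + 1L])
  lt <- log(vapply(idx, devalk_theta_sum, numeric(1), n = n))
  stats::cov(lx, lt) / stats::var(lt)
}

#' de Valk's complete-data extreme quantile estimator
#'
#' Extrapolates from an intermediate order statistic using harmonic sums and
#' a tail-regularity function:
#' \deqn{\hat q(z) = X_{n-l_n:n}\,
#'   \exp\bigl\{ g(\vartheta_{l_n,n})\, h_\theta(z/\vartheta_{l_n+1,n}) \bigr\},}
#' with \eqn{h_\theta(\lambda) = (\lambda^\theta - 1)/\theta} for
#' \eqn{\theta \ne 0} and \eqn{h_0 = \log\lambda}, and
#' \eqn{z = -\log(\text{target probability})}.  For Pareto-type tails
#' \eqn{\theta = 1} and \eqn{g(x) = c\,x}; when `g_slope` is `NULL` the slope
#' `c` is estimated by the Hill estimator on the top `l_n + 1` order
#' statistics.
#'
#' @param sample complete positive i.i.d. sample.
#' @param z exceedance exponent `-log(target probability)` (> 0).
#' @param l_n intermediate order count, `1 <= l_n < n` (default
#'   `floor(n/10)`).
#' @param theta tail-model exponent (1 for Pareto-type tails, 0 for
#'   Weibull-type tails).
#' @param g_slope for `theta = 1`: slope of `g(x) = c x`, estimated by
#'   [hill_estimate()] when `NULL`; for `theta = 0`: the constant level of
#'   `g`, estimated by [devalk_g0_estimate()] when `NULL`.
#' @return The quantile estimate.
#' @export
devalk_quantile <- function(sample, z, l_n = max(1L, floor(length(sample) / 10)),
                            theta = 1, g_slope = NULL) {
  n <- length(sample)
  stopifnot(z > 0)
  if (!(l_n >= 1 && l_n < n)) stop("'l_n' must satisfy 1 <= l_n < n", call. = FALSE)
  xs <- sort(sample)
  anchor <- xs[n - l_n]
  g_val <- if (theta == 0) {
    if (is.null(g_slope)) devalk_g0_estimate(sample, l_n) else g_slope
  } else {
    chat <- if (is.null(g_slope)) hill_estimate(sample, l_n + 1L) else g_slope
    chat * devalk_theta_sum(l_n, n)
  }
  lam <- z / devalk_theta_sum(l_n + 1L, n)
  devalk_extrapolate(anchor, g_val, lam, theta)
}

#' @rdname devalk_quantile
#' @param anchor intermediate order statistic \eqn{X_{n-l_n:n}}.
#' @param g_val value of the regularity function \eqn{g(\vartheta_{l_n,n})}.
#' @param lam extrapolation ratio \eqn{z/\vartheta_{l_n+1,n}}.
#' @export
devalk_extrapolate <- function(anchor, g_val, lam, theta = 1) {
  stopifnot(anchor > 0, lam > 0)
  h <- if (theta != 0) (lam^theta - 1) / theta else log(lam)
  anchor * exp(g_val * h)
}
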