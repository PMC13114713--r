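test_that("staircase walk follows the up-and-down rule", {
  # a latent model that never fails produces an arithmetic ramp
  cfg <- staircase_config(5, 15, 10, "gaussian", c(1e6, 1))
  run <- staircase_run(cfg, seed = 1)
  expect_equal(run$levels, 5 + 15 * (0:9))
  expect_true(all(run$outcomes == 0L))
  # a latent model that always fails walks straight down
  cfg2 <- staircase_config(5, 1, 10, "gaussian", c(-1e6, 1))
  run2 <- staircase_run(cfg2, seed = 1)
  expect_equal(run2$levels, 5 - (0:9))
  # deterministic latent R = const: alternates once the constant is bracketed
  cfg3 <- staircase_config(10, 1, 20, "gaussian", c(10.5, 1e-9))
  run3 <- staircase_run(cfg3, seed = 2)
  tail_lv <- tail(run3$levels, 10)
  expect_true(all(tail_lv %in% c(10, 11)))
  expect_equal(staircase_run(cfg, 42), staircase_run(cfg, 42))
})

test_that("staircase failure fraction matches the Markov transition-matrix oracle", {
  cfg <- staircase_config(5, 15, 100, "exponential", 0.2)
  want <- staircase_expected_failure_fraction(cfg)
  reps <- 400
  fr <- numeric(reps)
  for (r in 1:reps) fr[r] <- mean(staircase_run(cfg, derive_seed(7, r))$outcomes)
  se <- sd(fr) / sqrt(reps)
  expect_lt(abs(mean(fr) - want), 3 * se)
})

test_that("staircase MLE solves the score equations", {
  # single level: closed-form rate
  lv <- rep(5, 40); y <- c(rep(1, 25), rep(0, 15))
  fit <- staircase_mle(lv, y, "exponential")
  expect_equal(unname(fit$par["rate"]), -log(1 - 25 / 40) / 5, tolerance = 1e-6)
  expect_equal(fit$quantile, -log(1 - 1e-3) / fit$par[["rate"]], tolerance = 1e-9)
  # Gaussian on two levels: the two probit equations solve exactly
  f1 <- 0.3; f2 <- 0.8; s1 <- 50; s2 <- 65
  z1 <- qnorm(f1); z2 <- qnorm(f2)
  sg <- (s2 - s1) / (z2 - z1); mu <- s1 - sg * z1
  lv <- c(rep(s1, 200), rep(s2, 200))
  y <- c(rep(1, round(200 * f1)), rep(0, round(200 * (1 - f1))),
         rep(1, round(200 * f2)), rep(0, round(200 * (1 - f2))))
  fit <- staircase_mle(lv, y, "gaussian")
  expect_equal(unname(fit$par["mean"]), mu, tolerance = 1e-5)
  expect_equal(unname(fit$par["sd"]), sg, tolerance = 1e-4)
  expect_error(staircase_mle(lv, rep(1, 400), "gaussian"), "separation")
})

test_that("CRM pieces match their closed forms", {
  expect_equal(crm_lambda_draw(0.5, 1), log(2))
  expect_equal(crm_lambda_draw(1 - exp(-1), 1), 1)
  expect_error(crm_lambda_draw(1, 1), "strictly inside")
  # posterior pseudo-counts: prior (2, 10), 3 failures in 10 trials
  expect_equal(crm_posterior(2, 10, 3, 10), c(shape1 = 5, shape2 = 16))
  # zero new data leaves the prior shape
  expect_equal(crm_posterior(2, 10, 0, 0), c(shape1 = 2, shape2 = 9))
  # Monte-Carlo mean of the implied rate matches quadrature of the integrand
  set.seed(8)
  draws <- rbeta(1e5, 2, 9)
  mc <- mean(crm_lambda_draw(draws, 1))
  quad <- integrate(function(p) -log(1 - p) * dbeta(p, 2, 9), 0, 1)$value
  expect_lt(abs(mc - quad), 3 * sd(crm_lambda_draw(draws, 1)) / sqrt(1e5))
})

test_that("CRM level selection is a brute-force argmin with monotone behavior", {
  set.seed(9)
  for (rep in 1:100) {
    lv <- sort(runif(sample(3:10, 1), 0.01, 5))
    lb <- runif(1, 0.01, 3)
    at <- runif(1, 1e-4, 0.3)
    got <- crm_select_level(lb, lv, at)
    d <- abs(1 - exp(-lb * lv) - at)
    expect_equal(got, lv[which.min(d)])
  }
  # larger rate estimates never select a larger level
  lv <- seq(0.5, 5, by = 0.5)
  sel <- sapply(c(0.05, 0.1, 0.5, 1, 2, 5), crm_select_level,
                levels = lv, alpha_target = 0.1)
  expect_true(all(diff(sel) <= 0))
})

test_that("CRM posterior concentrates on the observed failure fraction", {
  post <- crm_posterior(2, 10, 3000, 10000)
  m <- post[["shape1"]] / (post[["shape1"]] + post[["shape2"]])
  v <- m * (1 - m) / (post[["shape1"]] + post[["shape2"]] + 1)
  expect_lt(abs(m - 0.3), 0.01)
  expect_lt(v, 1e-4)
})

test_that("CRM runs are reproducible and their trace is coherent", {
  cfg <- crm_config(levels = seq(0.001, 0.01, length.out = 10))
  r1 <- crm_run(cfg, true_rate = 0.2, seed = 3)
  r2 <- crm_run(cfg, true_rate = 0.2, seed = 3)
  expect_identical(r1, r2)
  expect_true(r1$q_alpha_est %in% cfg$levels)
  expect_equal(r1$trace$cum_trials, cfg$J_per_iter * cfg$N_iter)
})

test_that("harmonic tail sums and the extrapolation formula are exact", {
  expect_equal(devalk_theta_sum(3, 3), 1 / 3)
  expect_equal(devalk_theta_sum(1, 3), 11 / 6)
  expect_equal(devalk_theta_sum(1, 50) - devalk_theta_sum(2, 50), 1)
  expect_error(devalk_theta_sum(4, 3), "k <= n")
  # anchor 10, g-value 0.5 * 1, ratio 3, theta 1: 10 * exp(0.5 * 2) = 10 e
  expect_equal(devalk_extrapolate(10, 0.5, 3, theta = 1), 10 * exp(1))
  # theta = 0 uses the log form
  expect_equal(devalk_extrapolate(10, 0.5, exp(2), theta = 0), 10 * exp(1))
})

test_that("de Valk's estimator anchors, scales, and tracks the GPD truth", {
  th <- gpd_params(0.8, 1.5)
  xs <- sample_latent("gpd", th, 250, seed = 17)
  n <- 250; l <- 25
  # z equal to the anchor's harmonic sum returns the intermediate order stat
  z0 <- devalk_theta_sum(l + 1, n)
  expect_equal(devalk_quantile(xs, z0, l_n = l), sort(xs)[n - l])
  # scale equivariance
  q1 <- devalk_quantile(xs, log(1e3), l_n = l)
  q2 <- devalk_quantile(3.7 * xs, log(1e3), l_n = l)
  expect_equal(q2, 3.7 * q1, tolerance = 1e-12)
  # median relative error over replicas is small and centered near zero
  reps <- 150
  re <- numeric(reps)
  truth <- gpd_quantile(1 - 1e-3, th)
  for (r in 1:reps) {
    s <- sample_latent("gpd", th, 250, seed = derive_seed(23, r))
    re[r] <- relative_error(devalk_quantile(s, log(1e3), l_n = 25, g_slope = 0.8),
                            truth)
  }
  expect_lt(abs(median(re)), 0.2)
})

test_that("the Weibull-tail regularity level is recovered from the sample", {
  wth <- weibull_params(3, 0.9)
  # on the ideal quantile function the regression slope is exactly 1/shape
  n <- 250; l <- 25
  ideal <- weibull_quantile(1 - exp(-vapply((n:1), devalk_theta_sum, numeric(1), n = n)), wth)
  expect_equal(devalk_g0_estimate(ideal, l), 1 / 0.9, tolerance = 1e-9)
  est <- numeric(100)
  for (r in 1:100) {
    s <- sample_latent("weibull", wth, n, seed = derive_seed(29, r))
    est[r] <- devalk_g0_estimate(s, l)
  }
  expect_lt(abs(mean(est) - 1 / 0.9), 0.2)
})
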