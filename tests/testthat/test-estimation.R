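test_that("empirical stage probability is the plain mean, with a count oracle", {
  expect_equal(empirical_p(c(1, 0, 1, 1)), 0.75)
  expect_equal(empirical_p(rep(0, 10)), 0)
  y <- sample_stage(gpd_params(1, 1), 1, 0, 50, seed = 123)
  tally <- 0L
  for (v in y) tally <- tally + as.integer(v == 1L)  # independent tally
  expect_equal(empirical_p(y), tally / 50)
  expect_error(empirical_p(integer(0)), "nonempty")
})

test_that("Wald interval matches the normal closed form and shrinks as K^(-1/2)", {
  iv <- wald_interval(0.25, 50, 0.2)
  expect_equal(unname(iv[1]), 0.17072, tolerance = 1e-4)
  expect_equal(unname(iv[2]), 0.32928, tolerance = 1e-4)
  # gamma near 1 collapses the interval onto p_hat
  iv1 <- wald_interval(0.25, 50, 0.999999)
  expect_lt(iv1[[2]] - iv1[[1]], 1e-5)
  # mirror symmetry in p_hat
  iva <- wald_interval(0.3, 40, 0.2); ivb <- wald_interval(0.7, 40, 0.2)
  expect_equal(unname(iva[1]), unname(1 - ivb[2]))
  # width scales like K^(-1/2) (using the K - 1 denominator)
  w <- function(K) diff(unname(wald_interval(0.25, K, 0.2)))
  expect_equal(w(101) / w(26), sqrt(25 / 100), tolerance = 1e-12)
  expect_error(wald_interval(0, 50, 0.2), "strictly inside")
  expect_error(wald_interval(0.5, 1, 0.2), "at least 2")
})

test_that("admissibility tests the implied conditional exceedance probability", {
  expect_true(is_admissible(1, 1, 2, 1, c(0, 1)))
  # GPD(1,1) conditional sf over a unit gap is 0.5
  expect_true(is_admissible(1, 1, 2, 1, c(0.49, 0.51)))
  expect_false(is_admissible(1, 1, 2, 1, c(0.51, 0.6)))
  # an exact-p configuration stays admissible for any gamma < 1
  th <- gpd_params(0.8, 1.5)
  s1 <- gpd_quantile(0.75, th)
  cond <- gpd_condition(th, s1)
  s2 <- s1 + gpd_quantile(0.75, cond)
  for (g in c(0.99, 0.5, 0.05)) {
    iv <- wald_interval(0.25, 50, g)
    expect_true(is_admissible(cond$c, cond$a, s2, s1, iv))
  }
})

test_that("backward objective matches hand-solved conditional quantiles", {
  # conditional median of GPD(1, 2) is 2, equal to the realized increment
  expect_equal(backward_objective(1, 1, 3, 1, 0.5), 0)
  # (1 + x/2)^(-1) = 0.75 gives x = 2/3
  expect_equal(backward_objective(1, 1, 3, 1, 0.75), 4 / 3, tolerance = 1e-12)
  # continuity/monotonicity of the underlying quantile in p_hat
  ph <- seq(0.05, 0.95, by = 0.05)
  q <- sapply(ph, function(p) gpd_quantile(1 - p, gpd_params(1, 2)))
  expect_true(all(diff(q) < 0))
  expect_error(backward_objective(1, 1, 1, 3, 0.5), "s_jm1 > s_jm2")
})

test_that("constrained minimizer equals exhaustive grid enumeration", {
  set.seed(31)
  for (rep in 1:8) {
    cfg <- estimator_config(grid_size = 20, refine = FALSE)
    s_jm2 <- runif(1, 0, 3)
    s_jm1 <- s_jm2 + runif(1, 0.5, 5)
    s_j <- s_jm1 + runif(1, 0.5, 8)
    p_hat <- runif(1, 0.15, 0.5)
    iv <- wald_interval(runif(1, 0.15, 0.4), 50, 0.2)
    got <- tryCatch(estimate_stage(s_jm2, s_jm1, s_j, p_hat, iv, cfg),
                    splitquant_estimation_error = function(e) NULL)
    want <- brute_force_stage_min(s_jm2, s_jm1, s_j, p_hat, iv, cfg)
    if (is.null(want)) {
      expect_null(got)
    } else {
      expect_equal(got$params$c, want$c)
      expect_equal(got$params$a, want$a)
      expect_equal(got$objective, want$objective)
    }
  }
})

test_that("a self-consistent admissible point attains objective zero", {
  th <- gpd_params(0.8, 1.5)
  s1 <- gpd_quantile(0.75, th)
  s2 <- s1 + gpd_quantile(0.75, gpd_condition(th, s1))
  s3 <- s2 + gpd_quantile(0.75, gpd_condition(th, s2))
  cfg <- estimator_config(refine = TRUE, grid_size = 60)
  iv <- wald_interval(0.25, 50, 0.2)
  est <- estimate_stage(s1, s2, s3, 0.25, iv, cfg)
  expect_lt(est$objective, 1e-6)
  # the refined minimizer reproduces the realized increment
  q <- gpd_quantile(0.75, gpd_condition(est$params, s1))
  expect_equal(q, s2 - s1, tolerance = 1e-5)
})

test_that("with a vacuous interval the estimator is the unconstrained minimizer", {
  cfg <- estimator_config(grid_size = 25, refine = FALSE)
  free <- estimate_stage(0, 2, 5, 0.25, c(lower = 0, upper = 1), cfg)
  g <- expand.grid(
    c = exp(seq(log(0.05), log(5), length.out = 25)),
    a = exp(seq(log(0.05), log(20), length.out = 25)))
  objs <- backward_objective(g$c, g$a, 2, 0, 0.25)
  expect_equal(free$objective, min(objs))
})

test_that("Bernoulli log-likelihood sums correctly and is flat in (c, a)", {
  y <- c(rep(1, 60), rep(0, 140))
  expect_equal(bernoulli_loglik(0.3, y), 60 * log(0.3) + 140 * log(0.7))
  # the binomial MLE in the probability maximizes the likelihood
  ll <- sapply(seq(0.05, 0.95, by = 0.01), bernoulli_loglik, outcomes = y)
  expect_equal(seq(0.05, 0.95, by = 0.01)[which.max(ll)], 0.3)
  expect_identical(bernoulli_loglik(0, y), -Inf)
  expect_identical(bernoulli_loglik(1, y), -Inf)
  # flatness: binary data at one threshold identify only a curve in (c, a);
  # the 1-unit likelihood region spans at least half the c range
  th <- gpd_params(0.8, 1.5)
  s1 <- gpd_quantile(0.75, th)
  y <- sample_stage(th, s1, 0, 200, seed = 99)
  cs <- exp(seq(log(0.05), log(5), length.out = 80))
  as <- exp(seq(log(0.05), log(20), length.out = 80))
  ll <- outer(cs, as, function(cc, aa)
    vapply(seq_along(cc), function(i)
      bernoulli_loglik(gpd_sf(s1, gpd_params(cc[i], aa[i])), y), numeric(1)))
  near_max_c <- range(cs[rowSums(ll >= max(ll) - 1) > 0])
  expect_gt(log(near_max_c[2] / near_max_c[1]), 0.5 * log(5 / 0.05) / 2)
})

test_that("Weibull shape recovery is exact on noiseless ladders and tracks truth under noise", {
  wth <- weibull_params(3, 0.9)
  p <- 0.25
  s <- weibull_quantile(1 - p^(1:4), wth)  # exact conditional ladder
  p_hats <- rep(p, 4)
  expect_equal(weibull_estimate_shape(s, p_hats), 0.9, tolerance = 1e-6)
  # two stages: bracketed root finding
  expect_equal(weibull_estimate_shape(s[1:2], p_hats[1:2]), 0.9, tolerance = 1e-6)
  # shape-1 geometry: equal increments and equal fractions return 1
  expect_equal(weibull_estimate_shape(c(1, 2, 3), c(0.3, 0.3, 0.3)), 1,
               tolerance = 1e-6)
  # noisy fractions at K = 50: mean recovered shape near truth over replicas
  est <- numeric(60)
  for (r in 1:60) {
    ph <- numeric(4)
    for (j in 1:4) {
      y <- sample_stage(wth, s[j], if (j == 1) 0 else s[j - 1], 50,
                        derive_seed(500 + r, j))
      n1 <- sum(y)
      ph[j] <- if (n1 %in% c(0, 50)) (n1 + 0.5) / 51 else n1 / 50
    }
    est[r] <- weibull_estimate_shape(s, ph)
  }
  expect_lt(abs(mean(est) - 0.9), 0.15)
})

test_that("the ML baseline maximizes the cumulated stage likelihood on its grid", {
  th <- gpd_params(0.8, 1.5)
  s <- c(3, 12, 40)
  n1 <- c(13, 12, 11); nt <- c(50, 50, 50)
  cfg <- estimator_config(grid_size = 15, refine = FALSE)
  fit <- ml_estimate(s, n1, nt, cfg)
  # independent recomputation of the attained log-likelihood
  ll_at <- function(cc, aa) {
    tot <- 0; prev <- 0
    for (l in seq_along(s)) {
      pil <- gpd_sf(s[l] - prev, gpd_condition(gpd_params(cc, aa), prev))
      tot <- tot + n1[l] * log(pil) + (nt[l] - n1[l]) * log(1 - pil)
      prev <- s[l]
    }
    tot
  }
  expect_equal(fit$loglik, ll_at(fit$params$c, fit$params$a), tolerance = 1e-12)
  cs <- exp(seq(log(0.05), log(5), length.out = 15))
  as <- exp(seq(log(0.05), log(20), length.out = 15))
  best <- max(outer(cs, as, Vectorize(ll_at)))
  expect_gte(fit$loglik + 1e-12, best)
})
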