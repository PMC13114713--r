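test_that("GPD survival, quantile and conditioning satisfy their closed forms", {
  th <- gpd_params(1, 1)
  expect_equal(gpd_sf(0, th), 1)
  expect_equal(gpd_sf(1, th), 0.5)
  expect_equal(gpd_quantile(0, th), 0)
  # printed true quantiles of the three reference parameter sets
  expect_lt(abs(gpd_quantile(1 - 1e-3, gpd_params(0.8, 1.5)) - 469.103), 1e-3)
  expect_lt(abs(gpd_quantile(1 - 1e-3, gpd_params(1.5, 1.5)) - 31621.777), 1e-3)
  expect_lt(abs(gpd_quantile(1 - 1e-3, gpd_params(1.5, 3)) - 63243.553), 1e-3)
  # conditioning shifts only the scale
  cond <- gpd_condition(gpd_params(0.8, 1.5), 10)
  expect_equal(cond$c, 0.8)
  expect_equal(cond$a, 9.5)
  # semigroup: condition by s then t == condition by s + t
  th2 <- gpd_params(0.8, 1.5)
  expect_equal(gpd_condition(gpd_condition(th2, 3), 4),
               gpd_condition(th2, 7))
  expect_error(gpd_params(0, 1), "strictly positive")
  expect_error(gpd_params(1, -1), "strictly positive")
  expect_error(gpd_sf(-1, th), "nonnegative")
  expect_error(gpd_quantile(1, th), "0, 1")
})

test_that("threshold-conditioning stability holds on random grids", {
  set.seed(11)
  for (rep in 1:20) {
    th <- gpd_params(runif(1, 0.1, 3), runif(1, 0.2, 5))
    s <- runif(1, 0, 50)
    x <- runif(5, 0, 100)
    lhs <- gpd_sf(x + s, th) / gpd_sf(s, th)
    rhs <- gpd_sf(x, gpd_condition(th, s))
    expect_lt(max(abs(lhs / rhs - 1)), 1e-12)
  }
})

test_that("survival/quantile round trips are exact where the survival is representable", {
  # past these ranges 1 - sf(x) rounds to 1 in double precision (the survival
  # underflows relative to 1), so the probability-scale round trip is tested
  # where it is numerically meaningful
  x <- 10^seq(-3, 4, length.out = 40)
  th <- gpd_params(0.8, 1.5)
  expect_lt(max(abs(gpd_quantile(1 - gpd_sf(x, th), th) / x - 1)), 1e-9)
  xw <- 10^seq(-3, log10(50), length.out = 40)
  wth <- weibull_params(3, 0.9)
  expect_lt(max(abs(weibull_quantile(1 - weibull_sf(xw, wth), wth) / xw - 1)), 1e-9)
})

test_that("Weibull closed forms match the printed reference quantiles", {
  expect_lt(abs(weibull_quantile(1 - 1e-3, weibull_params(3, 0.9)) - 25.69), 0.005)
  expect_lt(abs(weibull_quantile(1 - 1e-3, weibull_params(3, 1.5)) - 10.88), 0.005)
  expect_lt(abs(weibull_quantile(1 - 1e-3, weibull_params(2, 1.5)) - 7.25), 0.005)
  expect_equal(weibull_sf(0, weibull_params(2, 1.5)), 1)
  expect_equal(weibull_quantile(0, weibull_params(2, 1.5)), 0)
})

test_that("scale-free Weibull conditional identities agree with direct sf ratios", {
  # equal increments under shape 1 reproduce memorylessness
  expect_equal(weibull_cond_log_sf(1, 2, 1, log(0.5)), log(0.5))
  expect_equal(weibull_cond_log_sf(1, 1, 2, log(0.5)), 0)
  # shape 2 doubling: (4 - 1) * log p, cross-checked against explicit scale
  scale <- 1 / sqrt(-log(0.25))  # makes P(R > 1) = 0.25
  wth <- weibull_params(scale, 2)
  expect_equal(weibull_cond_log_sf(1, 2, 2, log(0.25)), 3 * log(0.25))
  expect_equal(weibull_cond_log_sf(1, 2, 2, log(0.25)),
               log(weibull_sf(2, wth) / weibull_sf(1, wth)), tolerance = 1e-12)
  # random admissible triples, both identities vs direct ratios
  set.seed(21)
  for (rep in 1:25) {
    wth <- weibull_params(runif(1, 0.5, 5), runif(1, 0.4, 3))
    s <- sort(runif(3, 0.1, 6))
    lp1 <- log(weibull_sf(s[1], wth))
    direct12 <- log(weibull_sf(s[2], wth)) - log(weibull_sf(s[1], wth))
    expect_equal(weibull_cond_log_sf(s[1], s[2], wth$shape, lp1), direct12,
                 tolerance = 1e-10)
    lp_cond <- direct12
    direct23 <- log(weibull_sf(s[3], wth)) - log(weibull_sf(s[2], wth))
    expect_equal(weibull_cond_log_sf3(s[1], s[2], s[3], wth$shape, lp_cond),
                 direct23, tolerance = 1e-10)
  }
  expect_error(weibull_cond_log_sf(2, 1, 1, log(0.5)), ">=")
})

test_that("Gamma-mixture representation reproduces the GPD survival function", {
  # c = 1, a = 1: the mixing law is Exp(1) and the transform is 1/(1 + x)
  th <- gpd_params(1, 1)
  expect_equal(gpd_sf_gamma_mixture(0, th), 1, tolerance = 1e-8)
  expect_equal(gpd_sf_gamma_mixture(3, th), 0.25, tolerance = 1e-8)
  for (cc in c(0.5, 0.8, 1.5)) {
    for (aa in c(1, 1.5, 3)) {
      th <- gpd_params(cc, aa)
      for (x in c(0, 0.5, 1, 10, 100)) {
        expect_lt(abs(gpd_sf_gamma_mixture(x, th) - gpd_sf(x, th)), 1e-6)
      }
    }
  }
})

test_that("transformed-GPD survival families are proper and match hand values", {
  base <- gpd_params(1, 1)
  # logarithmic form at x = 1: G = 0.5, so 1 - log(1.5)/log(2)
  sp <- transformed_gpd_spec(base, "logarithmic")
  expect_equal(transformed_gpd_sf(1, sp), 1 - log(1.5) / log(2), tolerance = 1e-12)
  xs <- seq(0, 200, length.out = 1000)
  for (form in c("exponential", "logarithmic", "root", "fraction")) {
    sp <- transformed_gpd_spec(gpd_params(0.8, 1.5), form, form_param = 2)
    w <- transformed_gpd_sf(xs, sp)
    expect_equal(w[1], 1)
    expect_true(all(diff(w) <= 1e-12))
    expect_true(all(w >= 0 & w <= 1))
    expect_lt(transformed_gpd_sf(1e9, sp), 1e-2)
  }
  expect_error(transformed_gpd_spec(base, "exponential", exponent = 1.5), "0, 1")
  expect_error(transformed_gpd_spec(base, "fraction", form_param = -1), "positive")
})

test_that("reciprocal quantile duality is an involution", {
  expect_equal(reciprocal_quantile(2), 0.5)
  expect_equal(reciprocal_quantile(reciprocal_quantile(469.103)), 469.103)
  expect_equal(reciprocal_quantile(469.103), 1 / 469.103)
  expect_error(reciprocal_quantile(0), "positive")
})

test_that("unconditional parameters are recovered from conditioned estimates", {
  th <- gpd_params(0.8, 1.5)
  expect_equal(recover_initial(gpd_params(0.8, 9.5), 10), th)
  expect_equal(recover_initial(th, 0), th)
  rt <- recover_initial(gpd_condition(th, 7.3), 7.3)
  expect_equal(rt$c, th$c)
  expect_equal(rt$a, th$a)
  bad <- recover_initial(gpd_params(2, 1), 5)
  expect_false(bad$valid)
})
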