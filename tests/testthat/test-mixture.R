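test_that("a pure exponential age sample recovers the death rate", {
  cfg <- sim_config(
    seed = 1, w_exp = 1,
    components = tibble::tibble(mean = numeric(), variance = numeric(),
                                weight = numeric())
  )
  x <- simulate_age_sample(1e4, cfg, seed = 4)
  fit <- fit_mixture(x$age, n_normals = 0, seed = 4)
  expect_gt(fit$death_rate, 1.79)
  expect_lt(fit$death_rate, 2.00)
  expect_equal(fit$n_normals, 0)
})

test_that("the fitted mixture is a proper density with a monotone EM trace", {
  x <- simulate_age_sample(3000, sim_config(seed = 1), seed = 6)
  fit <- fit_mixture(x$age, n_normals = 2, seed = 6)
  integral <- stats::integrate(function(v) duplidate:::mixture_density(v, fit),
                               0, fit$upper, rel.tol = 1e-9)$value
  expect_equal(integral, 1, tolerance = 1e-6)
  expect_true(all(diff(fit$trace) > -1e-6))
  expect_equal(fit$w_exp + sum(fit$components$weight), 1, tolerance = 1e-9)
  expect_true(all(fit$components$variance > 0))
  gl <- glance(fit)
  expect_equal(gl$n_obs, 3000)
  expect_s3_class(autoplot(fit, ages = x$age), "ggplot")
})

test_that("input contracts are enforced", {
  expect_error(fit_mixture(runif(20, 0, 2)), ">= 50")
  expect_error(fit_mixture(c(runif(100, 0, 2), 2.5)), "lie in")
  expect_error(select_model(runif(10, 0, 2)), ">= 50")
})

test_that("parameter recovery on the polyploid-like mixture", {
  # replicates at reduced n; measured Monte-Carlo accuracy at n = 4000:
  # peak means to ~2-4%, death rate to ~20-25% (the rate is weakly
  # identified against the broad truncated old peak; see the vignette)
  errs <- sapply(1:6, function(s) {
    x <- simulate_age_sample(4000, sim_config(seed = 1), seed = 20 + s)
    f <- fit_mixture(x$age, n_normals = 2, seed = s)
    c(lam = abs(f$death_rate - 1.892) / 1.892,
      mu1 = abs(f$components$mean[1] - 0.185) / 0.185,
      mu2 = abs(f$components$mean[2] - 1.650) / 1.650)
  })
  expect_lt(median(errs["mu1", ]), 0.05)
  expect_lt(median(errs["mu2", ]), 0.05)
  expect_lt(median(errs["lam", ]), 0.30)
})

test_that("model selection by KS p-value finds the right peak count", {
  cfg_exp <- sim_config(
    seed = 1, w_exp = 1,
    components = tibble::tibble(mean = numeric(), variance = numeric(),
                                weight = numeric())
  )
  x0 <- simulate_age_sample(1500, cfg_exp, seed = 31)
  sel0 <- select_model(x0$age, seed = 31)
  expect_equal(sel0$n_normals, 0)
  expect_equal(nrow(sel0$selection), 4)

  x2 <- simulate_age_sample(2000, sim_config(seed = 1), seed = 32)
  sel2 <- select_model(x2$age, seed = 32)
  expect_equal(sel2$n_normals, 2)
  # a 0-normal fit cannot explain the bimodal sample as well
  p0 <- sel2$selection$ks_pvalue[sel2$selection$n_normals == 0]
  p2 <- sel2$selection$ks_pvalue[sel2$selection$n_normals == 2]
  expect_lt(p0, p2)
})

test_that("component mass matches the closed-form truncated normal", {
  fit <- structure(list(
    death_rate = 1.892, w_exp = 0.8,
    components = tibble::tibble(mean = 0.185, variance = 0.08^2,
                                weight = 0.2),
    upper = 2
  ), class = "ks_mixture_fit")
  m <- component_mass(fit, 1, c(0, 0.4), n_pairs = 5000)
  z <- pnorm((2 - 0.185) / 0.08) - pnorm(-0.185 / 0.08)
  expected <- 5000 * 0.2 *
    (pnorm((0.4 - 0.185) / 0.08) - pnorm(-0.185 / 0.08)) / z
  expect_equal(m, expected, tolerance = 1e-12)
  expect_lt(abs(m - 996), 996 * 0.03)
  # the full window returns the component's whole weight; empty none
  expect_equal(component_mass(fit, 1, c(0, 2), 5000), 1000, tolerance = 1e-9)
  expect_equal(component_mass(fit, 1, c(0.3, 0.3), 5000), 0)
})

test_that("a fit reproduces data simulated from itself", {
  x <- simulate_age_sample(3000, sim_config(seed = 1), seed = 41)
  fit <- fit_mixture(x$age, n_normals = 2, seed = 41)
  cfg_fit <- sim_config(
    seed = 1, death_rate = fit$death_rate,
    components = fit$components, w_exp = fit$w_exp
  )
  ok <- vapply(1:10, function(s) {
    fresh <- simulate_age_sample(1000, cfg_fit, seed = 500 + s)
    suppressWarnings(
      stats::ks.test(fresh$age,
                     function(q) mixture_cdf(q, fit))$p.value
    ) > 0.05
  }, logical(1))
  expect_gte(sum(ok), 9)
})
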