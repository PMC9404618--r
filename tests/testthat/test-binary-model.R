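# The hierarchical logistic engine, checked against independent oracles:
# a precision-weighted normal approximation on collapsed margins, a dense
# numeric integration of the exact two-parameter posterior, and the prior
# itself when the likelihood carries no treatment information.

neutral <- normal_prior("neutral", 0, 0.355)

test_that("collapsed two-arm margins reproduce the normal-approximation oracle", {
  # 643/1465 vs 639/1462 deaths, one site, no covariates: the exact posterior
  # is well approximated by precision-weighting the prior with the likelihood
  d <- data.frame(
    site_id = "S1",
    arm = rep(c(1, 0), c(1465, 1462)),
    death90 = c(rep(1:0, c(643, 1465 - 643)), rep(1:0, c(639, 1462 - 639)))
  )
  spec <- binary_model_spec("death90", neutral, covariates = character(0))
  fit <- fit_quiet(fit_binary_model(d, spec,
                                    quick_sampler(chains = 4, warmup = 500,
                                                  kept = 1500, seed = 4)))
  th <- draws_of(fit, "theta")

  lo <- log((643 / (1465 - 643)) / (639 / (1462 - 639)))
  se <- sqrt(1 / 643 + 1 / (1465 - 643) + 1 / 639 + 1 / (1462 - 639))
  post_mean <- (lo / se^2) / (1 / se^2 + 1 / 0.355^2)
  post_sd <- 1 / sqrt(1 / se^2 + 1 / 0.355^2)
  expect_lt(abs(median(th) - post_mean), 3 * post_sd / sqrt(1000))
  expect_lt(abs(sd(th) - post_sd), 0.005)
  expect_equal(round(median(exp(th)), 2), 1.01)
})

test_that("relabelling the arms mirrors the treatment posterior", {
  d <- small_trial(n = 500, seed = 51)
  d <- complete_cases(d, binary_fields())
  spec <- binary_model_spec("death90", neutral)
  f1 <- fit_quiet(fit_binary_model(d, spec, quick_sampler(kept = 800, seed = 2)))
  d_flip <- d
  d_flip$arm <- 1 - d$arm
  f2 <- fit_quiet(fit_binary_model(d_flip, spec, quick_sampler(kept = 800, seed = 2)))
  t1 <- draws_of(f1, "theta")
  t2 <- draws_of(f2, "theta")
  mcse <- sd(t1) / sqrt(200) + sd(t2) / sqrt(200)
  expect_lt(abs(median(t1) + median(t2)), 3 * mcse)
})

test_that("the posterior median is monotone across the prior spectrum", {
  d <- small_trial(n = 500, seed = 52)
  d <- complete_cases(d, binary_fields())
  meds <- vapply(build_theoretical_priors(), function(p) {
    spec <- binary_model_spec("death90", p)
    fit <- fit_quiet(fit_binary_model(d, spec, quick_sampler(kept = 800, seed = 3)))
    median(draws_of(fit, "theta"))
  }, 0)
  expect_lt(meds[["optimistic"]], meds[["neutral"]])
  expect_lt(meds[["neutral"]], meds[["pessimistic"]])
})

test_that("site effects track observed site death rates", {
  d <- generate_trial(sim_config(n_patients = 4000, n_sites = 12,
                                 tau_site = 0.6, seed = 53))
  d <- complete_cases(d, binary_fields())
  spec <- binary_model_spec("death90", neutral)
  fit <- fit_quiet(fit_binary_model(d, spec, quick_sampler(kept = 600, seed = 5)))
  site_rates <- tapply(d$death90, d$site_id, mean)
  u_means <- vapply(names(site_rates), function(s) {
    mean(draws_of(fit, paste0("u[", s, "]")))
  }, 0)
  expect_gt(cor(qlogis(pmin(pmax(site_rates, 0.02), 0.98)), u_means), 0.7)
})

test_that("a constant treatment column returns the prior (sampler validation)", {
  for (p in list(neutral, normal_prior("optimistic", -0.257, 0.249))) {
    spec <- binary_model_spec("death90", p)
    pp <- prior_predictive_check(spec, quick_sampler(kept = 1500, seed = 6))
    th <- draws_of(pp, "theta")
    ess <- pp$diagnostics$per_parameter
    ess_th <- ess$ess[ess$parameter == "theta"]
    expect_lt(abs(mean(th) - p$mean), 3 * p$sd / sqrt(ess_th))
    expect_lt(abs(sd(th) - p$sd), 3 * p$sd / sqrt(2 * (ess_th - 1)) + 0.01)
  }
})

test_that("one-site no-covariate posterior agrees with dense numeric integration", {
  set.seed(54)
  n <- 200
  arm <- rbinom(n, 1, 0.5)
  y <- rbinom(n, 1, plogis(-0.3 + 0.2 * arm))
  d <- data.frame(site_id = "S1", arm = arm, death90 = y)
  spec <- binary_model_spec("death90", neutral, covariates = character(0))
  fit <- fit_quiet(fit_binary_model(d, spec,
                                    quick_sampler(chains = 4, warmup = 500,
                                                  kept = 1000, seed = 7)))
  th <- draws_of(fit, "theta")

  # dense integration of the exact (intercept, theta) posterior
  s1 <- sum(y[arm == 1]); n1 <- sum(arm == 1)
  s0 <- sum(y[arm == 0]); n0 <- n - n1
  b0g <- seq(-3, 2.5, length.out = 501)
  thg <- seq(-3, 3, length.out = 601)
  ll <- outer(b0g, thg, function(b0, th) {
    s0 * b0 - n0 * log1p(exp(b0)) + s1 * (b0 + th) - n1 * log1p(exp(b0 + th))
  })
  lp <- ll + (dt(b0g / 2.5, 3, log = TRUE) - log(2.5)) +
    rep(dnorm(thg, 0, 0.355, log = TRUE), each = length(b0g))
  w <- exp(lp - max(lp))
  cdf <- cumsum(colSums(w))
  cdf <- cdf / cdf[length(cdf)]
  Fth <- approxfun(thg, cdf, yleft = 0, yright = 1)
  ks <- max(abs(seq_along(th) / length(th) - Fth(sort(th))))
  expect_lt(ks, 0.05)
})

test_that("degenerate inputs raise identifiability and validation errors", {
  d <- small_trial(n = 100, seed = 55)
  d <- complete_cases(d, binary_fields())
  spec <- binary_model_spec("death90", neutral)
  one_arm <- d[d$arm == 1, ]
  expect_error(fit_binary_model(one_arm, spec, quick_sampler()), "single-arm")
  expect_error(fit_binary_model(d[0, ], spec, quick_sampler()), "data")
  d_na <- d
  d_na$death90[1] <- NA
  expect_error(fit_binary_model(d_na, spec, quick_sampler()), "complete_cases")
  d_bad <- d
  d_bad$death90 <- d_bad$death90 + 0.5
  expect_error(fit_binary_model(d_bad, spec, quick_sampler()), "death90")
})
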