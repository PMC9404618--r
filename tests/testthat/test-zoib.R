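# The zero-one-inflated beta machinery: closed-form mixture identities, the
# blocked Metropolis sampler cross-checked against an independent JAGS fit of
# the identical model, parameter recovery from the generating law, and the
# day-difference summary layer.

test_that("the mixture mean identity holds and is monotone", {
  expect_equal(expected_scaled_value(zoib_params(0, 0.4, 0.6, 2)), 0.6)
  expect_equal(expected_scaled_value(zoib_params(1, 1, 0.6, 2)), 1)
  expect_equal(expected_scaled_value(zoib_params(0.3, 0.4, 0.5, 2)), 0.47)
  expect_equal(90 * expected_scaled_value(zoib_params(0.3, 0.4, 0.5, 2)), 42.3)

  mus <- seq(0.05, 0.95, by = 0.05)
  vals <- vapply(mus, function(m) expected_scaled_value(zoib_params(0.3, 0.4, m, 2)), 0)
  expect_true(all(diff(vals) > 0))
  cois <- seq(0, 1, by = 0.1)
  vals <- vapply(cois, function(cc) expected_scaled_value(zoib_params(0.3, cc, 0.5, 2)), 0)
  expect_true(all(diff(vals) > 0))
})

test_that("the sampler agrees with an independent JAGS fit of the same model", {
  skip_if_not_installed("rjags")
  set.seed(61)
  n <- 400; S <- 8
  site <- sample.int(S, n, replace = TRUE)
  arm <- rbinom(n, 1, 0.5); x1 <- rbinom(n, 1, 0.5)
  u <- rnorm(S, 0, 0.3)
  zoi <- plogis(-0.5 + 0.3 * arm); coi <- plogis(-0.8 - 0.2 * arm)
  mu <- plogis(0.3 - 0.2 * arm + 0.3 * x1 + u[site]); phi <- 3
  B <- rbinom(n, 1, zoi); O <- rbinom(n, 1, coi)
  y <- ifelse(B == 1, O * 90, 90 * rbeta(n, mu * phi, (1 - mu) * phi))
  d <- data.frame(site_id = sprintf("S%02d", site), arm = arm, sepsis = x1,
                  krt_free_days = y)
  spec <- zoib_model_spec("krt_free_days", covariates = "sepsis")
  fit <- fit_quiet(fit_zoib(d, spec, sampler_config(chains = 4, warmup_draws = 1200,
                                                    kept_draws_per_chain = 2000,
                                                    thin = 3, seed = 9)))

  ii <- which(y > 0 & y < 90); ib <- which(y == 0 | y == 90)
  mod <- "
  model {
    for (i in 1:n) { isb[i] ~ dbern(pz[i]); logit(pz[i]) <- g0 + g1*arm[i] }
    for (j in 1:nb) { isone[j] ~ dbern(pc[j]); logit(pc[j]) <- h0 + h1*armb[j] }
    for (k in 1:ni) {
      yi[k] ~ dbeta(mu[k]*phi, (1-mu[k])*phi)
      logit(mu[k]) <- c0 + ct*armi[k] + c1*x1i[k] + us[sitei[k]]
    }
    for (s in 1:S) { us[s] ~ dnorm(0, prec_u) }
    prec_u ~ dgamma(1.5, 3*inva); inva ~ dgamma(0.5, 0.16)
    tau <- 1/sqrt(prec_u)
    g0 ~ dt(0, 0.16, 3); h0 ~ dt(0, 0.16, 3); c0 ~ dt(0, 0.16, 3)
    g1 ~ dnorm(0, 1); h1 ~ dnorm(0, 1); ct ~ dnorm(0, 1); c1 ~ dnorm(0, 1)
    phi ~ dgamma(0.01, 0.01)
  }"
  dat <- list(isb = as.integer(y == 0 | y == 90), arm = arm, n = n,
              isone = as.integer(y[ib] == 90), armb = arm[ib], nb = length(ib),
              yi = y[ii] / 90, armi = arm[ii], x1i = x1[ii],
              sitei = as.integer(factor(site[ii])), ni = length(ii),
              S = length(unique(site[ii])))
  inits <- lapply(1:3, function(k) list(.RNG.name = "base::Mersenne-Twister",
                                        .RNG.seed = 200 + k))
  jm <- rjags::jags.model(textConnection(mod), data = dat, inits = inits,
                          n.chains = 3, quiet = TRUE)
  update(jm, 1500, progress.bar = "none")
  sm <- rjags::coda.samples(jm, c("g0", "g1", "h0", "h1", "c0", "ct", "c1",
                                  "phi", "tau"),
                            n.iter = 8000, thin = 4, progress.bar = "none")
  mj <- as.matrix(sm)
  map <- c(g0 = "zoi_intercept", g1 = "zoi_arm", h0 = "coi_intercept",
           h1 = "coi_arm", c0 = "mu_intercept", ct = "mu_arm",
           c1 = "mu_sepsis", phi = "phi", tau = "tau_site")
  for (v in names(map)) {
    mine <- draws_of(fit, map[[v]])
    ref_sd <- sd(mj[, v])
    expect_lt(abs(mean(mine) - mean(mj[, v])), 0.15 * ref_sd)
    expect_lt(abs(sd(mine) / ref_sd - 1), 0.15)
  }
})

test_that("the sampler recovers generating ZOIB parameters per arm", {
  set.seed(62)
  n_per_arm <- 1500
  truth <- list(standard = zoib_params(0.35, 0.25, 0.60, 2.5),
                accelerated = zoib_params(0.45, 0.15, 0.55, 2.5))
  arm <- rep(0:1, each = n_per_arm)
  y <- numeric(2 * n_per_arm)
  for (a in 0:1) {
    p <- truth[[a + 1]]
    idx <- which(arm == a)
    b <- rbinom(n_per_arm, 1, p$zoi)
    o <- rbinom(n_per_arm, 1, p$coi)
    y[idx] <- ifelse(b == 1, o * 90, 90 * rbeta(n_per_arm, p$mu * p$phi,
                                                (1 - p$mu) * p$phi))
  }
  d <- data.frame(site_id = "S1", arm = arm, krt_free_days = y)
  spec <- zoib_model_spec("krt_free_days", covariates = character(0))
  fit <- fit_quiet(fit_zoib(d, spec, sampler_config(chains = 2, warmup_draws = 800,
                                                    kept_draws_per_chain = 2000,
                                                    thin = 2, seed = 10)))
  g0 <- draws_of(fit, "zoi_intercept"); g1 <- draws_of(fit, "zoi_arm")
  h0 <- draws_of(fit, "coi_intercept"); h1 <- draws_of(fit, "coi_arm")
  c0 <- draws_of(fit, "mu_intercept"); ct <- draws_of(fit, "mu_arm")
  post <- list(
    list(plogis(g0), truth$standard$zoi), list(plogis(g0 + g1), truth$accelerated$zoi),
    list(plogis(h0), truth$standard$coi), list(plogis(h0 + h1), truth$accelerated$coi),
    list(plogis(c0), truth$standard$mu), list(plogis(c0 + ct), truth$accelerated$mu)
  )
  for (p in post) {
    expect_lt(abs(median(p[[1]]) - p[[2]]), 3 * sd(p[[1]]))
  }
})

test_that("degenerate and invalid day data are refused", {
  d <- data.frame(site_id = "S1", arm = rep(0:1, 50), krt_free_days = 90)
  spec <- zoib_model_spec("krt_free_days", covariates = character(0))
  expect_error(fit_zoib(d, spec, quick_sampler()), "boundary")
  d$krt_free_days <- seq(-1, 98, length.out = 100)
  expect_error(fit_zoib(d, spec, quick_sampler()), "krt_free_days")
  d$krt_free_days <- runif(100, 1, 89)
  d$arm <- 0
  expect_error(fit_zoib(d, spec, quick_sampler()), "arm")
})

test_that("rescaling the day scale leaves the fit unchanged", {
  set.seed(63)
  d <- small_trial(n = 200, seed = 64,
                   miss_krt_free_by_arm = c(standard = 0, accelerated = 0))
  spec90 <- zoib_model_spec("krt_free_days", covariates = character(0))
  f90 <- fit_quiet(fit_zoib(d, spec90, quick_sampler(kept = 300, seed = 3)))
  d180 <- d
  d180$krt_free_days <- d$krt_free_days * 2  # doubling is exact in floating point
  spec180 <- zoib_model_spec("krt_free_days", scale_max = 180, covariates = character(0))
  f180 <- fit_quiet(fit_zoib(d180, spec180, quick_sampler(kept = 300, seed = 3)))
  expect_equal(f90$draws, f180$draws, tolerance = 1e-12)
})

test_that("day differences are coherent and null under identical arms", {
  set.seed(65)
  n <- 2000
  base <- list(
    zoi_intercept = rnorm(n, -0.4, 0.1), zoi_arm = rep(0, n),
    coi_intercept = rnorm(n, -1, 0.1), coi_arm = rep(0, n),
    mu_intercept = rnorm(n, 0.3, 0.1), mu_arm = rep(0, n),
    phi = rexp(n) + 1
  )
  meta <- list(outcome = "krt_free_days", covariates = character(0), scale_max = 90, n = 10)
  dr <- fake_draws(base, model = "zoib", meta = meta)
  d <- data.frame(x = 1)
  spec <- zoib_model_spec("krt_free_days", covariates = character(0))
  s <- day_difference(dr, d, spec, force = TRUE)
  expect_equal(s$median_diff, 0)
  expect_equal(s$p_within_1day, 1)
  expect_equal(s$p_within_mcid, 1)
  expect_equal(s$p_at_least_mcid_benefit, 0)

  # complementarity of the direction probabilities
  shifted <- base
  shifted$mu_arm <- rnorm(n, 0, 0.3)
  dr2 <- fake_draws(shifted, model = "zoib", meta = meta)
  s2 <- day_difference(dr2, d, spec, force = TRUE)
  g0 <- shifted$zoi_intercept; c0 <- shifted$mu_intercept; ca <- shifted$mu_arm
  diff <- 90 * ((plogis(g0) * plogis(shifted$coi_intercept) +
                   (1 - plogis(g0)) * plogis(c0 + ca)) -
                  (plogis(g0) * plogis(shifted$coi_intercept) +
                     (1 - plogis(g0)) * plogis(c0)))
  expect_equal(s2$p_more_days + mean(diff <= 0), 1, tolerance = 1e-12)
  expect_equal(s2$median_diff, median(diff), tolerance = 1e-9)
})
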