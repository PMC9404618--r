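test_that("the generator is deterministic and its output honours the invariants", {
  cfg <- sim_config(n_patients = 500, n_sites = 20, seed = 11)
  d1 <- generate_trial(cfg)
  d2 <- generate_trial(cfg)
  expect_identical(d1, d2)

  expect_equal(nrow(d1), 500)
  expect_silent(validate_trial_dataset(d1))
  expect_lte(length(unique(d1$site_id)), 20)
  expect_true(all(d1$arm %in% 0:1))
  expect_true(all(is.na(d1$krt_free_days) |
                    (d1$krt_free_days >= 0 & d1$krt_free_days <= 90)))
  dead <- d1$survivor == 0
  expect_true(all(is.na(d1$krt_dep90[dead])))
  expect_true(all(is.na(d1$rehosp90[dead])))
  expect_identical(d1$survivor, 1L - d1$death90)

  # a different seed gives different data
  expect_false(identical(d1, generate_trial(sim_config(n_patients = 500,
                                                       n_sites = 20, seed = 12))))
})

test_that("empirical prevalences and mortality converge to the configured law", {
  n <- 20000
  d <- generate_trial(sim_config(n_patients = n, n_sites = 168, theta = 0, seed = 21))
  se_p <- function(p) sqrt(p * (1 - p) / n)

  expect_lt(abs(mean(d$sepsis) - 0.57), 3 * se_p(0.57))
  expect_lt(abs(mean(d$surgical) - 0.33), 3 * se_p(0.33))
  expect_lt(abs(mean(d$ckd) - 0.44), 3 * se_p(0.44))
  expect_lt(abs(mean(d$death90) - 0.44), 3 * se_p(0.44))

  # null treatment effect: arm-wise death rates agree within Monte Carlo error
  r1 <- mean(d$death90[d$arm == 1]); n1 <- sum(d$arm == 1)
  r0 <- mean(d$death90[d$arm == 0]); n0 <- sum(d$arm == 0)
  se_diff <- sqrt(r1 * (1 - r1) / n1 + r0 * (1 - r0) / n0)
  expect_lt(abs(r1 - r0), 3 * se_diff)
  expect_lt(abs(mean(d$arm) - 0.5), 3 * se_p(0.5))
})

test_that("day endpoints honour both boundaries under degenerate inflation", {
  par90 <- zoib_params(zoi = 1, coi = 1, mu = 0.5, phi = 2)
  cfg <- sim_config(
    n_patients = 300, n_sites = 5, seed = 3,
    zoib_params_by_arm = list(
      krt_free_days = list(standard = par90, accelerated = par90),
      hosp_free_days = list(standard = par90, accelerated = par90)),
    miss_krt_free_by_arm = c(standard = 0, accelerated = 0)
  )
  d <- generate_trial(cfg)
  expect_true(all(d$krt_free_days == 90))
  expect_true(all(d$hosp_free_days == 90))
})

test_that("deaths concentrate day-endpoint mass at zero via the coupling", {
  base <- sim_config(n_patients = 6000, n_sites = 30, seed = 9)
  d <- generate_trial(base)
  p0_dead <- mean(d$krt_free_days[d$death90 == 1] == 0, na.rm = TRUE)
  p0_alive <- mean(d$krt_free_days[d$death90 == 0] == 0, na.rm = TRUE)
  expect_gt(p0_dead, 0.5)
  expect_lt(p0_alive, 0.2)

  no_link <- sim_config(n_patients = 6000, n_sites = 30, seed = 9, death_zero_link = 0)
  d0 <- generate_trial(no_link)
  krt <- base$zoib_params_by_arm$krt_free_days$standard
  expect_lt(abs(mean(d0$krt_free_days == 0, na.rm = TRUE) -
                  krt$zoi * (1 - krt$coi)),
            3 * sqrt(0.08 * 0.92 / 6000) + 0.02)
})

test_that("missingness injection is MCAR within arm and complete_cases undoes it", {
  d <- small_trial(n = 600, seed = 31,
                   miss_krt_free_by_arm = c(standard = 0, accelerated = 0))
  expect_false(anyNA(d$krt_free_days))

  # zero rates: identity
  same <- inject_missingness(d, list(krt_free_days = c(standard = 0, accelerated = 0)), 7)
  expect_identical(same, d)
  expect_identical(complete_cases(same, "krt_free_days"), d)

  # saturation: every accelerated value missing, every standard value kept
  sat <- inject_missingness(d, list(krt_free_days = c(standard = 0, accelerated = 1)), 7)
  expect_true(all(is.na(sat$krt_free_days[sat$arm == 1])))
  expect_false(anyNA(sat$krt_free_days[sat$arm == 0]))
  expect_identical(sat[names(sat) != "krt_free_days"], d[names(d) != "krt_free_days"])

  # published rate on a full-size accelerated arm: expected count 27
  big <- data.frame(patient_id = as.character(1:2927),
                    site_id = "S1", arm = rep(c(1L, 0L), c(1465, 1462)),
                    sepsis = 0L, surgical = 0L, ckd = 0L, death90 = 0L,
                    krt_free_days = 45, hosp_free_days = 45, survivor = 1L,
                    krt_dep90 = 0L, rehosp90 = 0L)
  rate <- 27 / 1465
  m <- inject_missingness(big, list(krt_free_days = c(standard = 0, accelerated = rate)), 13)
  n_miss <- sum(is.na(m$krt_free_days))
  expect_true(all(m$arm[is.na(m$krt_free_days)] == 1))
  expect_lt(abs(n_miss - 27), 3 * sqrt(1465 * rate * (1 - rate)) + 1e-9)
  expect_equal(nrow(complete_cases(m, "krt_free_days")), 2927 - n_miss)

  # row order is preserved by filtering
  kept <- complete_cases(m, "krt_free_days")
  expect_identical(kept$patient_id, big$patient_id[!is.na(m$krt_free_days)])

  # degenerate: everything missing leaves an empty dataset
  all_gone <- inject_missingness(d, list(krt_free_days = c(standard = 1, accelerated = 1)), 5)
  expect_equal(nrow(complete_cases(all_gone, "krt_free_days")), 0)
})

test_that("validation errors name the offending field", {
  expect_error(sim_config(n_patients = 10, n_sites = 20), "n_sites")
  expect_error(sim_config(prev_sepsis = 1.4), "prev_sepsis")
  expect_error(sim_config(tau_site = -1), "tau_site")
  expect_error(sim_config(death_zero_link = 2), "death_zero_link")
  d <- small_trial(n = 50, seed = 1)
  expect_error(inject_missingness(d, list(nonexistent = c(0, 0)), 1), "unknown")
  expect_error(inject_missingness(d, list(arm = c(0, 0)), 1), "protected")
  expect_error(complete_cases(d, character(0)), "fields")
  expect_error(complete_cases(d, "no_such_column"), "no_such_column")
})

test_that("CSV and YAML round trips preserve data and config", {
  d <- small_trial(n = 120, seed = 41)
  csv <- tempfile(fileext = ".csv")
  write_trial_csv(d, csv)
  d2 <- read_trial_csv(csv)
  expect_equal(d2$krt_free_days, d$krt_free_days, tolerance = 1e-12)
  expect_identical(d2$site_id, d$site_id)
  expect_identical(d2$krt_dep90, d$krt_dep90)

  cfg <- sim_config(n_patients = 120, n_sites = 6, seed = 41, theta = -0.1)
  yml <- tempfile(fileext = ".yaml")
  sim_config_to_yaml(cfg, yml)
  cfg2 <- sim_config_from_yaml(yml)
  expect_equal(cfg2$theta, cfg$theta)
  expect_equal(cfg2$beta0, cfg$beta0, tolerance = 1e-6)
  expect_equal(cfg2$zoib_params_by_arm$krt_free_days$standard$mu,
               cfg$zoib_params_by_arm$krt_free_days$standard$mu)
  expect_identical(generate_trial(cfg2)$death90, generate_trial(cfg)$death90)

  # unknown keys are rejected, not ignored
  bad <- tempfile(fileext = ".yaml")
  writeLines(c("n_patients: 10", "n_sites: 2", "typo_key: 1"), bad)
  expect_error(sim_config_from_yaml(bad), "typo_key")
})
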