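# Shared fixtures: small seeded datasets and reduced sampler settings so the
# default suite stays fast; full-scale checks live in test-acceptance.R.

small_trial <- function(n = 400, n_sites = 10, seed = 5, ...) {
  generate_trial(sim_config(n_patients = n, n_sites = n_sites, seed = seed, ...))
}

quick_sampler <- function(chains = 2, warmup = 300, kept = 500, seed = 1, thin = 1) {
  sampler_config(chains = chains, warmup_draws = warmup,
                 kept_draws_per_chain = kept, seed = seed, thin = thin)
}

binary_fields <- function(outcome = "death90") {
  c(outcome, "arm", "site_id", "sepsis", "surgical", "ckd")
}

fit_quiet <- function(expr) suppressWarnings(expr)

# independent exhaustive shortest-window HDI search (the oracle the fast
# implementation is checked against)
hdi_oracle <- function(draws, mass = 0.95) {
  x <- sort(draws)
  n <- length(x)
  k <- ceiling(mass * n)
  best <- c(-Inf, Inf)
  for (i in seq_len(n - k + 1)) {
    if (x[i + k - 1] - x[i] < best[2] - best[1]) best <- c(x[i], x[i + k - 1])
  }
  best
}

# fabricate a posterior_draws object from per-parameter draw vectors (2 chains)
fake_draws <- function(values, model = "binary_logistic", meta = list()) {
  n <- length(values[[1]])
  stopifnot(n %% 2 == 0)
  arr <- array(NA_real_, dim = c(n / 2, 2, length(values)),
               dimnames = list(NULL, NULL, names(values)))
  for (j in seq_along(values)) arr[, , j] <- values[[j]]
  bayeskrt:::new_posterior_draws(arr, model = model, meta = meta)
}
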