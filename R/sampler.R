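#' MCMC sampler settings
#'
#' Shared settings for all model fits. `kept_draws_per_chain` defaults to
#' 2000 so that, with 4 chains, the slowest-mixing parameter (the site SD)
#' clears the ESS > 1000 convergence gate at default settings.
#' `target_accept` is an advisory adaptation target: the Gibbs engine used for
#' the logistic models has no such knob and ignores it; the Metropolis blocks
#' of the zero-one-inflated beta sampler adapt their proposal scales to the
#' standard random-walk targets internally.
#'
#' @param chains Number of chains, at least 2.
#' @param warmup_draws Warmup (adaptation) iterations per chain, discarded.
#' @param kept_draws_per_chain Retained iterations per chain.
#' @param seed Integer seed; per-chain seeds are derived from it.
#' @param target_accept Advisory acceptance target in (0, 1).
#' @param thin Keep every `thin`-th post-warmup iteration. Random-walk
#'   components (the zero-one-inflated beta sampler) decorrelate slowly per
#'   iteration but iterate cheaply, so thinning raises the effective sample
#'   size per kept draw at modest cost; the default for those fits is set by
#'   the pipeline.
#' @return An object of class `sampler_config`.
#' @export
sampler_config <- function(chains = 4, warmup_draws = 1000,
                           kept_draws_per_chain = 2000, seed = 1,
                           target_accept = 0.9, thin = 1) {
  chains <- check_count(chains, "chains", min = 2L)
  warmup_draws <- check_count(warmup_draws, "warmup_draws", min = 1L)
  kept_draws_per_chain <- check_count(kept_draws_per_chain, "kept_draws_per_chain", min = 1L)
  seed <- check_count(seed, "seed", min = 0L)
  thin <- check_count(thin, "thin", min = 1L)
  check_number(target_accept, "target_accept", 0, 1,
               strict_lower = TRUE, strict_upper = TRUE)
  structure(list(chains = chains, warmup_draws = warmup_draws,
                 kept_draws_per_chain = kept_draws_per_chain,
                 seed = seed, target_accept = target_accept, thin = thin),
            class = "sampler_config")
}

convergence_warning <- function(diag) {
  warning(warningCondition(
    sprintf("MCMC did not meet the convergence gates: %s", diag$message),
    class = "bayeskrt_convergence_warning"
  ))
}
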