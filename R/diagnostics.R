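# MCMC convergence diagnostics: rank-normalized split R-hat and bulk
# effective sample size, with the gates max R-hat < 1.01 and min ESS > 1000.
# The rank-normalized split variants are the modern defaults for these
# statistics; the gate thresholds are fixed by the analysis plan.

split_chains <- function(mat) {
  n <- nrow(mat)
  half <- floor(n / 2)
  if (half < 2) stop_invalid("draws", "need at least 4 iterations per chain")
  cbind(mat[seq_len(half), , drop = FALSE],
        mat[(n - half + 1):n, , drop = FALSE])
}

rank_normalize <- function(mat) {
  S <- length(mat)
  z <- stats::qnorm((rank(mat, ties.method = "average") - 3 / 8) / (S + 1 / 4))
  matrix(z, nrow = nrow(mat), ncol = ncol(mat))
}

rhat_basic <- function(mat) {
  n <- nrow(mat)
  W <- mean(apply(mat, 2, stats::var))
  B <- n * stats::var(colMeans(mat))
  var_plus <- (n - 1) / n * W + B / n
  sqrt(var_plus / W)
}

# biased autocovariance (divisor n) via FFT
autocovariance <- function(x) {
  n <- length(x)
  x <- x - mean(x)
  M <- stats::nextn(2 * n)
  f <- stats::fft(c(x, rep(0, M - n)))
  Re(stats::fft(f * Conj(f), inverse = TRUE))[seq_len(n)] / (M * n)
}

ess_basic <- function(mat) {
  n <- nrow(mat)
  m <- ncol(mat)
  acov <- apply(mat, 2, autocovariance)           # n x m, biased, lag 0 first
  chain_var <- acov[1, ] * n / (n - 1)
  W <- mean(chain_var)
  var_plus <- (n - 1) / n * W + if (m > 1) stats::var(colMeans(mat)) else 0
  if (var_plus <= 0) return(NA_real_)
  rho <- 1 - (W - rowMeans(acov)) / var_plus      # rho[1] is lag 0 (=~1)
  # Geyer initial positive + monotone sequence on paired sums
  max_pairs <- floor((n - 1) / 2)
  tau <- -1
  prev <- Inf
  for (k in 0:max_pairs) {
    i <- 2 * k + 1                                 # 1-based index of lag 2k
    if (i + 1 > n) break
    pair <- rho[i] + rho[i + 1]
    if (k > 0 && pair < 0) break
    pair <- min(pair, prev)
    prev <- pair
    tau <- tau + 2 * pair
  }
  tau <- max(tau, 1 / log10(n * m + 10))           # guard against tau < 1
  (n * m) / tau
}

#' Rank-normalized split R-hat of a single parameter
#'
#' @param mat Iteration x chain matrix of draws (>= 2 chains).
#' @return The R-hat statistic; `NA` if the draws are constant.
#' @export
mcmc_rhat <- function(mat) {
  mat <- as.matrix(mat)
  if (ncol(mat) < 2) stop_invalid("draws", "R-hat needs at least 2 chains")
  if (isTRUE(all.equal(stats::sd(mat), 0)) || any(apply(mat, 2, stats::sd) == 0)) {
    return(NA_real_)
  }
  rhat_basic(rank_normalize(split_chains(mat)))
}

#' Bulk effective sample size of a single parameter
#'
#' @param mat Iteration x chain matrix of draws.
#' @return The bulk ESS; `NA` if the draws are constant.
#' @export
mcmc_ess_bulk <- function(mat) {
  mat <- as.matrix(mat)
  if (stats::sd(mat) == 0 || any(apply(mat, 2, stats::sd) == 0)) return(NA_real_)
  ess_basic(rank_normalize(split_chains(mat)))
}

#' Convergence diagnostics with the analysis gates
#'
#' Computes rank-normalized split R-hat and bulk ESS for every parameter and
#' flags the fit as converged iff `max(rhat) < 1.01` and `min(ess) > 1000`.
#' Constant (zero-variance) parameter chains yield `NA` diagnostics and a
#' non-converged flag with an explanatory message rather than an error.
#'
#' @param draws A `posterior_draws` object, or an iteration x chain matrix for
#'   a single parameter.
#' @return An object of class `mcmc_diagnostics`: list with `per_parameter`
#'   (data.frame of `parameter`, `rhat`, `ess`), `converged`, and `message`.
#' @export
compute_diagnostics <- function(draws) {
  if (inherits(draws, "posterior_draws")) {
    arr <- draws$draws
  } else if (is.matrix(draws)) {
    arr <- array(draws, dim = c(nrow(draws), ncol(draws), 1),
                 dimnames = list(NULL, NULL, "parameter"))
  } else {
    stop_invalid("draws", "must be a posterior_draws object or a matrix")
  }
  if (dim(arr)[2] < 2) stop_invalid("draws", "diagnostics need at least 2 chains")
  pars <- dimnames(arr)[[3]]
  rhat <- ess <- rep(NA_real_, length(pars))
  for (j in seq_along(pars)) {
    m <- arr[, , j, drop = TRUE]
    if (is.null(dim(m))) m <- matrix(m, ncol = dim(arr)[2])
    if (stats::sd(m) == 0 || any(apply(m, 2, stats::sd) == 0)) next
    rhat[j] <- mcmc_rhat(m)
    ess[j] <- mcmc_ess_bulk(m)
  }
  flat <- is.na(rhat)
  converged <- !any(flat) && max(rhat) < 1.01 && min(ess) > 1000
  msg <- if (any(flat)) {
    sprintf("zero-variance draws for: %s", paste(pars[flat], collapse = ", "))
  } else if (!converged) {
    sprintf("max R-hat %.4f (gate < 1.01), min ESS %.0f (gate > 1000)",
            max(rhat), min(ess))
  } else {
    "all parameters pass the R-hat < 1.01 and ESS > 1000 gates"
  }
  structure(list(
    per_parameter = data.frame(parameter = pars, rhat = rhat, ess = ess,
                               stringsAsFactors = FALSE),
    converged = converged,
    message = msg
  ), class = "mcmc_diagnostics")
}

#' @export
print.mcmc_diagnostics <- function(x, ...) {
  cat(sprintf("<mcmc_diagnostics> converged: %s\n  %s\n", x$converged, x$message))
  invisible(x)
}
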