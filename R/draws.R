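# Container for MCMC output: a [iteration, chain, parameter] array with
# convergence diagnostics and model metadata attached.

new_posterior_draws <- function(arr, model, meta = list()) {
  stopifnot(is.array(arr), length(dim(arr)) == 3L, !is.null(dimnames(arr)[[3]]))
  x <- structure(list(draws = arr, model = model, meta = meta,
                      diagnostics = NULL),
                 class = "posterior_draws")
  x$diagnostics <- compute_diagnostics(x)
  x
}

#' @export
print.posterior_draws <- function(x, ...) {
  d <- dim(x$draws)
  cat(sprintf("<posterior_draws> %s: %d iterations x %d chains x %d parameters\n",
              x$model, d[1], d[2], d[3]))
  dg <- x$diagnostics
  cat(sprintf("  converged: %s (max R-hat %.4f, min bulk ESS %.0f)\n",
              dg$converged, max(dg$per_parameter$rhat, na.rm = TRUE),
              min(dg$per_parameter$ess, na.rm = TRUE)))
  head_pars <- utils::head(dimnames(x$draws)[[3]], 8)
  cat("  parameters:", paste(head_pars, collapse = ", "),
      if (d[3] > 8) sprintf("... (+%d)", d[3] - 8) else "", "\n")
  invisible(x)
}

#' Number of retained posterior draws (all chains pooled)
#' @param x A `posterior_draws` object.
#' @return Integer draw count.
#' @export
n_draws <- function(x) {
  stopifnot(inherits(x, "posterior_draws"))
  dim(x$draws)[1] * dim(x$draws)[2]
}

#' Parameter names of a draws object
#' @param x A `posterior_draws` object.
#' @return Character vector.
#' @export
parameter_names <- function(x) {
  stopifnot(inherits(x, "posterior_draws"))
  dimnames(x$draws)[[3]]
}

#' Extract draws of one parameter
#'
#' @param x A `posterior_draws` object.
#' @param parameter Parameter name.
#' @param pooled If `TRUE` (default) return one vector with chains
#'   concatenated; otherwise an iteration x chain matrix.
#' @return Numeric vector or matrix.
#' @export
draws_of <- function(x, parameter, pooled = TRUE) {
  stopifnot(inherits(x, "posterior_draws"))
  if (!parameter %in% parameter_names(x)) {
    stop_invalid("parameter", sprintf("'%s' not found", parameter))
  }
  m <- x$draws[, , parameter, drop = TRUE]
  if (is.null(dim(m))) m <- matrix(m, ncol = dim(x$draws)[2])
  if (pooled) as.vector(m) else m
}

#' @export
as.data.frame.posterior_draws <- function(x, ...) {
  d <- dim(x$draws)
  pars <- dimnames(x$draws)[[3]]
  data.frame(
    chain = rep(rep(seq_len(d[2]), each = d[1]), times = d[3]),
    iteration = rep(seq_len(d[1]), times = d[2] * d[3]),
    parameter = rep(pars, each = d[1] * d[2]),
    value = as.vector(x$draws),
    stringsAsFactors = FALSE
  )
}

#' Write posterior draws to CSV in long format
#'
#' Columns: `chain`, `iteration`, `parameter`, `value`.
#'
#' @param x A `posterior_draws` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_draws_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

# mcmc.list (coda) -> [iter, chain, parameter] array
mcmc_list_to_array <- function(mcl) {
  n_iter <- nrow(mcl[[1]])
  pars <- colnames(mcl[[1]])
  arr <- array(NA_real_, dim = c(n_iter, length(mcl), length(pars)),
               dimnames = list(NULL, NULL, pars))
  for (ch in seq_along(mcl)) arr[, ch, ] <- as.matrix(mcl[[ch]])
  arr
}
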