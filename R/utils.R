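# Internal helpers: validation, seeding, small numerics.

stop_invalid <- function(field, msg) {
  stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}

check_number <- function(x, field, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop_invalid(field, "must be a single non-missing number")
  }
  lo_ok <- if (strict_lower) x > lower else x >= lower
  hi_ok <- if (strict_upper) x < upper else x <= upper
  if (!lo_ok || !hi_ok) {
    stop_invalid(field, sprintf(
      "must be in %s%s, %s%s but is %g",
      if (strict_lower) "(" else "[", format(lower),
      format(upper), if (strict_upper) ")" else "]", x
    ))
  }
  invisible(x)
}

check_prob <- function(x, field) check_number(x, field, 0, 1)

check_count <- function(x, field, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != round(x) || x < min) {
    stop_invalid(field, sprintf("must be an integer >= %d", min))
  }
  invisible(as.integer(x))
}

is_binary01 <- function(x) {
  all(is.na(x) | x %in% c(0, 1))
}

# log(1 + exp(x)) without overflow
log1pexp <- function(x) {
  out <- x
  small <- x < 18
  out[small] <- log1p(exp(x[small]))
  big <- !small & x < 33.3
  out[big] <- x[big] + exp(-x[big])
  out
}

#' Derive a reproducible sub-stream seed from a root seed and a label
#'
#' One root seed drives every source of randomness in the pipeline; per-fit
#' and per-stage seeds are derived deterministically from it so that seeds
#' never collide across endpoints and priors.
#'
#' @param seed Integer root seed.
#' @param label Character tag naming the sub-stream (e.g. "primary:neutral").
#' @return A single integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, label) {
  codes <- utf8ToInt(label)
  h <- sum(codes * seq_along(codes)) %% 1000003
  as.integer((abs(as.numeric(seed)) * 7919 + h * 31 + 1) %% 2147483646) + 1L
}

# Evaluate `code` under `seed`, restoring the caller's RNG state afterwards.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
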