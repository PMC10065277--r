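# Internal helpers shared across modules.

#' Evaluate code under a fixed RNG seed, restoring the caller's RNG state
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

#' Truncated-normal draws by rejection (bounds are several sd away in practice)
#' @noRd
rnorm_trunc <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (sd == 0) return(rep(pmin(pmax(mean, lower), upper), n))
  out <- numeric(n)
  todo <- seq_len(n)
  for (i in 1:1000) {
    out[todo] <- stats::rnorm(length(todo), mean, sd)
    todo <- todo[out[todo] < lower | out[todo] > upper]
    if (!length(todo)) return(out)
  }
  # pathological parameterisation: fall back to clamping
  out[todo] <- pmin(pmax(stats::rnorm(length(todo), mean, sd), lower), upper)
  out
}

#' User-facing error (exit code 1 in the CLI)
#' @noRd
stop_user <- function(...) {
  stop(errorCondition(sprintf(...), class = c("proxhrv_user_error", "error")))
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}
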