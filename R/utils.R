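# internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(...) stop(sprintf(...), call. = FALSE)

warnf <- function(...) warning(sprintf(...), call. = FALSE)

#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `code` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so package internals never disturb user-level randomness.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# cheap deterministic content checksum (order-sensitive); used for model
# training fingerprints, not cryptography
content_checksum <- function(...) {
  parts <- list(...)
  acc <- 0
  for (p in parts) {
    v <- if (is.character(p)) utf8ToInt(paste(p, collapse = "\x1f")) else as.numeric(p)
    v <- v[is.finite(v)]
    i <- seq_along(v)
    acc <- (acc + sum((v * 1e4) %% 7919 * ((i %% 97) + 1))) %% 2147483647
  }
  sprintf("%x-%d", as.integer(acc), length(parts))
}
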