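## Evaluate expr under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Derive a reproducible child seed
#'
#' Expands one global seed into per-subject / per-condition child seeds via a
#' counter-based integer hash, so any subset of a cohort can be regenerated
#' without replaying the full random stream. Results stay below 2^31.
#'
#' @param seed integer parent seed.
#' @param ... integers or strings identifying the stream (e.g. subject
#'   index, condition name).
#' @return a single integer seed.
#' @export
childSeed <- function(seed, ...) {
  parts <- list(...)
  h <- as.numeric(seed) %% 2147483647
  for (p in parts) {
    codes <- if (is.character(p)) utf8ToInt(paste(p, collapse = "")) else
      as.numeric(p)
    for (v in codes) h <- (h * 69069 + (v %% 2147483647) + 1) %% 2147483647
  }
  as.integer(h)
}
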