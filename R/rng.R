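#' Derive a per-component seed from a master seed
#'
#' Expands one master seed into independent deterministic streams, one per
#' named component, so that adding a stage to a pipeline never perturbs
#' another stage's draws. The result is always a valid 32-bit integer seed.
#'
#' @param seed Master integer seed.
#' @param component Character name of the consuming component.
#' @return An integer seed.
#' @export
derive_seed <- function(seed, component) {
  if (!is.numeric(seed) || length(seed) != 1L || seed != round(seed))
    stop("`seed` must be a single integer", call. = FALSE)
  h <- sum(utf8ToInt(component) * seq_along(utf8ToInt(component)))
  as.integer((abs(seed) * 7919 + h * 104729) %% .Machine$integer.max)
}

# evaluate `expr` without disturbing the caller's RNG state
with_preserved_rng <- function(expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  expr
}
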