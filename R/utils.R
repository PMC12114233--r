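# internal helpers shared across modules

# Run `expr` under a fixed RNG state without disturbing the caller's stream.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("`seed` must be a single integer", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a stage-specific seed from a master seed
#'
#' Hashes a master seed together with a stage label so independent pipeline
#' stages draw from unrelated but reproducible streams. Result is always a
#' non-negative integer below 2^31.
#'
#' @param seed master integer seed.
#' @param stage character label of the stage.
#' @return a single integer seed.
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.character(stage), length(stage) == 1L)
  # iterated LCG over the label bytes; all arithmetic stays below 2^53
  h <- as.numeric(seed) %% 2147483647
  for (b in utf8ToInt(stage))
    h <- (h * 69069 + b * 2654435 + 1) %% 2147483647
  as.integer(h)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
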