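# Internal helpers shared across modules.

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG
# state; with seed = NULL the expression runs on the current stream.
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("seed must be a single integer or NULL")
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a per-stage child seed from a master seed
#'
#' Stages of a pipeline run are seeded independently so any stage can be
#' rerun in isolation.  The child seed is a deterministic polynomial hash of
#' the stage name combined with the master seed, reduced modulo a prime
#' below 2^31.
#'
#' @param masterSeed single integer master seed.
#' @param stage character stage name.
#' @return single integer seed.
#' @export
stageSeed <- function(masterSeed, stage) {
  stopifnot(is.numeric(masterSeed), length(masterSeed) == 1L,
            is.character(stage), length(stage) == 1L)
  p <- 2147483629
  h <- as.numeric(masterSeed) %% p
  for (k in utf8ToInt(stage)) h <- (h * 131 + k) %% p
  as.integer(h)
}

stopIfNot <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)

# half-open interval membership [a, b)
inHalfOpen <- function(x, bounds) x >= bounds[1] & x < bounds[2]
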