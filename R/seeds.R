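# Seed plumbing: every stochastic operation in the package takes an explicit
# integer seed and must not disturb the caller's RNG stream.

with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("seed must be a single integer", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a reproducible sub-seed
#'
#' Mixes a master seed with arbitrary string/integer components (participant
#' index, pipeline stage name, ...) into a deterministic 31-bit sub-seed,
#' so that per-participant streams are reproducible independently of
#' execution order. Uses an FNV-1a style byte hash.
#'
#' @param master integer master seed.
#' @param ... components (coerced to character) identifying the consumer.
#' @return A single integer in `[0, 2^31 - 1]`.
#' @export
derive_seed <- function(master, ...) {
  key <- paste(c(format(as.integer(master)), vapply(list(...), function(x)
    paste(format(x), collapse = ","), character(1))), collapse = "|")
  bytes <- utf8ToInt(key)
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), as.integer(b))
    h <- (h * 16777619) %% 2^31
  }
  as.integer(h %% (2^31 - 1))
}
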