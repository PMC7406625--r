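#' Derive a reproducible sub-stream seed
#'
#' All stochastic operations in the package draw their randomness from a
#' single user-supplied integer seed. Independent stages (population
#' simulation, germination sampling, permutation scans, ...) each derive
#' their own sub-stream seed by hashing the master seed together with a
#' stage label, so any stage can be re-run in isolation and still
#' reproduce its output bit for bit.
#'
#' @param seed master integer seed.
#' @param ... stage labels (coerced to character) mixed into the hash.
#' @return an integer in `[0, 2^31 - 2]` suitable for [set.seed()].
#' @export
substream_seed <- function(seed, ...) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  m <- 2147483647 # 2^31 - 1, keeps the hash within R's integer range
  h <- as.double(abs(seed)) %% m
  for (id in c(...)) {
    for (ch in utf8ToInt(as.character(id))) {
      h <- (h * 31 + ch) %% m
    }
  }
  as.integer(h)
}

# internal: evaluate with a local RNG state so callers' streams are untouched
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv())
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(expr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# internal: consistent message channel so pipelines can silence logging
dq_log <- function(..., quiet = getOption("dormqtl.quiet", FALSE)) {
  if (!isTRUE(quiet)) message(...)
  invisible(NULL)
}
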