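# Internal helpers shared across modules.

# Run `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards. All exported stochastic operations funnel
# through this so identical seeds give byte-identical results.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
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
  }
  force(code)
}

# Derive a child seed from a base seed and a stage label, staying inside
# 32-bit integer range.
derive_seed <- function(seed, label) {
  h <- digest::digest(list(as.integer(seed), as.character(label)), algo = "crc32")
  as.integer(strtoi(substr(h, 1, 7), base = 16L))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

assert_that <- function(ok, msg) {
  if (!isTRUE(ok)) stop(msg, call. = FALSE)
  invisible(TRUE)
}
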