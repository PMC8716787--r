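#' @keywords internal
"_PACKAGE"

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
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
  })
  set.seed(as.integer(seed))
  force(expr)
}

#' Derive a child seed from a master seed and a key
#'
#' Deterministic, platform-independent seed derivation used everywhere the
#' package fans out randomness (permutations, CV folds, replicates, per-pair
#' screening). A polynomial rolling hash of the key string is combined with
#' the master seed modulo 2^31 - 1, so derived seeds are valid R integers and
#' results are independent of execution order or worker count.
#'
#' @param master integer master seed.
#' @param ... components (coerced to character) identifying the child stream,
#'   e.g. `derive_seed(seed, "perm", i)`.
#' @return a single integer in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(master, ...) {
  key <- paste(c(format(as.integer(master)), vapply(list(...), function(x)
    paste(format(x), collapse = ","), character(1))), collapse = "|")
  m <- 2147483647
  h <- as.integer(master) %% m
  for (ch in utf8ToInt(key)) {
    h <- (h * 31 + ch) %% m
  }
  as.integer(h %% (m - 2L) + 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ggi <- function(...) stop(..., call. = FALSE)

is_count <- function(x) {
  length(x) == 1 && is.numeric(x) && !is.na(x) && x == floor(x) && x >= 1
}
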