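#' Evaluate code under a temporary RNG seed
#'
#' Sets the seed, evaluates `code`, and restores the caller's RNG state so
#' seeded package functions never disturb the global random stream.  A `NULL`
#' seed evaluates `code` against the current stream unchanged.
#'
#' @param seed integer seed or `NULL`.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

#' Derive a deterministic child seed from a root seed and a stream tag
#'
#' One root seed drives a whole run; each stage or colony gets its own
#' substream keyed by name, so reordering stages never silently changes
#' results.  The derivation is a fixed integer hash kept below 2^31.
#'
#' @param seed integer root seed.
#' @param tag character stream label (stage or colony name).
#' @return integer seed.
#' @export
derive_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(tag))
  h <- 0
  for (b in utf8ToInt(tag)) h <- (h * 131 + b) %% 2147483629
  as.integer((abs(seed) %% 2147483629 * 48271 + h) %% 2147483629 + 1)
}
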