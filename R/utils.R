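#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

## Draw n child seeds from one master seed without disturbing the caller's
## RNG stream more than once; values stay below 2^31 (R integers).
spawn_seeds <- function(master_seed, n) {
  stopifnot(is.numeric(master_seed), length(master_seed) == 1L, n >= 1)
  old <- get0(".Random.seed", envir = globalenv(), ifnotfound = NULL)
  set.seed(as.integer(master_seed))
  s <- sample.int(.Machine$integer.max - 1L, n)
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  s
}

stop_config <- function(...) stop(sprintf(...), call. = FALSE)

is_count <- function(x, min = 1) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= min && x == round(x)
}
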