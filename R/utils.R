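`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive deterministic sub-seeds from a master seed
#'
#' Expands one master seed into `n` independent 32-bit sub-seeds by a fixed
#' counter scheme, so that the stream assigned to molecule `i` does not move
#' when molecules are added after it.
#'
#' @param master Integer master seed.
#' @param n Number of sub-seeds to derive.
#' @return Integer vector of length `n`, each usable with [set.seed()].
#' @export
derive_seeds <- function(master, n) {
  stopifnot(is.numeric(master), length(master) == 1L, is.finite(master))
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(master))
  sample.int(.Machine$integer.max - 1L, n)
}

# stop() with a sprintf-style message and no call in the condition
abort <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_positive <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0))
    abort("`%s` must be a positive finite number", name)
  invisible(x)
}

check_nonneg <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0))
    abort("`%s` must be a non-negative finite number", name)
  invisible(x)
}
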