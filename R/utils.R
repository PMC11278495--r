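`%||%` <- function(x, y) if (is.null(x)) y else x

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Derive a stage seed from a master seed
#'
#' Each pipeline stage draws from its own named stream so that changing one
#' stage's randomness never silently shifts another's. Kept below 2^31 - 1.
#'
#' @param master integer master seed.
#' @param stage character stage name.
#' @return an integer seed.
#' @export
derive_seed <- function(master, stage) {
  offsets <- c(
    simulate = 101L, split = 211L, model = 307L, forest = 401L,
    contrast = 467L, ablation = 503L, narrative = 601L, eval = 701L
  )
  off <- offsets[[stage]] %||% (sum(utf8ToInt(stage)) %% 997L)
  as.integer((as.double(master) * 7919 + off) %% 2147483646) + 1L
}

assert_scalar_int <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != floor(x)) {
    stop(sprintf("`%s` must be a single integer", what), call. = FALSE)
  }
  invisible(as.integer(x))
}
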