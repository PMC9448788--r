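# Classed error conditions so callers can catch specific failure modes.
# Every error raised by the package inherits "aslbids_error"; the condition
# subclass encodes the failure kind (e.g. "aslbids_missing_file").

asl_abort <- function(class, message, ..., call = NULL) {
  cond <- structure(
    class = c(paste0("aslbids_", class), "aslbids_error", "error", "condition"),
    list(message = message, call = call, ...)
  )
  stop(cond)
}

#' @keywords internal
`%||%` <- function(x, y) if (is.null(x)) y else x

# Evaluate `code` under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
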