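#' @keywords internal
"_PACKAGE"

# Evaluate `code` under a locally seeded RNG, restoring the caller's RNG
# state afterwards.  seed = NULL means "use the current RNG stream".
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if_not_scalar_prob <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0) || any(x > 1))
    stop(sprintf("`%s` must be a probability in [0, 1]", name), call. = FALSE)
  invisible(x)
}
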