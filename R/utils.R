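# internal helpers: classed conditions and seed scoping

abort <- function(msg, class, call. = FALSE) {
  stop(errorCondition(msg, class = c(class, "scdemd_error")))
}

#' @noRd
stopifnot_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    abort(sprintf("`%s` must be a single finite number", name), "scdemd_config_error")
  if (positive && x <= 0)
    abort(sprintf("`%s` must be > 0", name), "scdemd_config_error")
  invisible(x)
}

# Run `expr` under `seed` without disturbing the caller's RNG stream.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    abort("`seed` must be a single finite number", "scdemd_config_error")
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic child seed from a master seed; stays inside 32-bit range.
derive_seed <- function(seed, i) {
  as.integer((as.double(seed) * 7919 + as.double(i) * 104729) %% 2147483647)
}
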