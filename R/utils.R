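# Internal helpers: classed conditions and seeded evaluation.

abort <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "npcquant_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

abort_validation <- function(msg, ...) abort(msg, "npcquant_validation_error", ...)
abort_domain     <- function(msg, ...) abort(msg, "npcquant_domain_error", ...)
abort_parse      <- function(msg, ...) abort(msg, "npcquant_parse_error", ...)

#' @noRd
stopifnot_scalar_number <- function(x, name, finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || (finite && !is.finite(x)))
    abort_validation(sprintf("'%s' must be a single finite number", name))
  invisible(x)
}

# Evaluate `expr` under a fixed seed without disturbing the caller's RNG
# stream.  All synthetic-data generators are pure functions of their spec
# (seed included); this is what makes regeneration bit-identical.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    abort_validation("'seed' must be a single integer")
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  expr
}
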