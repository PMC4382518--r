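# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Classed conditions so callers can distinguish error families programmatically.
kt_stop <- function(subclass, msg, ..., call = sys.call(-1)) {
  stop(errorCondition(msg, ..., class = c(subclass, "kt_error"),
                      call = call))
}

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    kt_stop("kt_input_error", "seed must be a single finite number")
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

kt_version_header <- function(seed = NULL, extra = character(0)) {
  v <- as.character(utils::packageVersion("kturnfold"))
  out <- sprintf("# kturnfold %s", v)
  if (!is.null(seed)) out <- c(out, sprintf("# seed=%s", format(seed)))
  c(out, extra)
}
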