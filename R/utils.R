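# Internal helpers: classed conditions and seeded evaluation.

qeeg_error <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "qeeg_error"),
                      call = call))
}

#' @noRd
abort_format    <- function(msg) qeeg_error(msg, "qeeg_format_error")
abort_integrity <- function(msg) qeeg_error(msg, "qeeg_integrity_error")
abort_param     <- function(msg) qeeg_error(msg, "qeeg_parameter_error")
abort_length    <- function(msg) qeeg_error(msg, "qeeg_length_error")
abort_domain    <- function(msg) qeeg_error(msg, "qeeg_domain_error")
abort_degenerate<- function(msg) qeeg_error(msg, "qeeg_degenerate_error")
abort_task      <- function(msg) qeeg_error(msg, "qeeg_task_error")
abort_io        <- function(msg) qeeg_error(msg, "qeeg_io_error")
abort_feature   <- function(msg) qeeg_error(msg, "qeeg_feature_error")

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG stream.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    abort_param("seed must be a single finite number")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a base seed and an index, staying inside the
# 32-bit signed integer range R requires.
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) * 69069 + 12345 * as.double(index)) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
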