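# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a deterministic sub-stream seed from a master seed
#'
#' Each pipeline stage draws from its own RNG sub-stream so that changing one
#' stage's consumption of random numbers does not perturb the others. The
#' sub-stream seed is a deterministic 31-bit hash of the master seed and a
#' stage label.
#'
#' @param seed master integer seed.
#' @param label character stage label.
#' @return an integer seed in [0, 2^31 - 1].
#' @keywords internal
substream_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(label))
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((abs(seed) * 7919 + h * 104729 + 12345) %% .Machine$integer.max)
}

# Evaluate `expr` with a locally-set RNG seed, restoring global RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

stop_ic <- function(..., class) {
  stop(structure(
    class = c(class, "icclock_error", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

check_aligned <- function(n_a, n_b, what_a, what_b) {
  if (n_a != n_b) {
    stop_ic(what_a, " (", n_a, ") and ", what_b, " (", n_b,
            ") are not aligned", class = "icclock_alignment_error")
  }
  invisible(TRUE)
}
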