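# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG seed, restoring the caller's RNG
# state afterwards so library functions never clobber user reproducibility.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

# Derive a child seed from a master seed; keeps results < 2^31 - 1.
derive_seed <- function(seed, index, salt = 0L) {
  as.integer((as.double(seed) * 48271 + index * 7919 + salt * 104729) %% 2147483587)
}

check_scalar_number <- function(x, name, positive = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      (positive && x <= 0)) {
    stop(sprintf("`%s` must be a single finite%s number", name,
                 if (positive) " positive" else ""), call. = FALSE)
  }
  invisible(x)
}
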