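#' Conventional seven-band frequency scheme for rodent ECoG
#'
#' The seven contiguous bands used throughout the package, in ascending
#' order: delta 0.5--4, theta 4.5--8, alpha 8.5--12, low-beta 12.5--20,
#' high-beta 20.5--30, low-gamma 30.5--40 and high-gamma 40.5--60 Hz.
#'
#' @return A data frame with columns `band` (short name used in feature
#'   column names), `low` and `high` (Hz).
#' @examples
#' band_scheme()
#' @export
band_scheme <- function() {
  data.frame(
    band = c("delta", "theta", "alpha", "lbeta", "hbeta", "lgamma", "hgamma"),
    low  = c(0.5, 4.5, 8.5, 12.5, 20.5, 30.5, 40.5),
    high = c(4.0, 8.0, 12.0, 20.0, 30.0, 40.0, 60.0),
    stringsAsFactors = FALSE
  )
}

# internal: validate a band scheme data frame
check_bands <- function(bands) {
  stopifnot(is.data.frame(bands), all(c("band", "low", "high") %in% names(bands)))
  if (any(bands$low >= bands$high)) {
    stop("each band must satisfy low < high", call. = FALSE)
  }
  if (is.unsorted(bands$low) || any(bands$high[-nrow(bands)] > bands$low[-1])) {
    stop("bands must be ascending and non-overlapping", call. = FALSE)
  }
  invisible(bands)
}

#' Vigilance state labels
#'
#' The three vigilance states scored per epoch, in canonical order.
#' @return `c("WAKE", "NREM", "REM")`
#' @export
vigilance_states <- function() c("WAKE", "NREM", "REM")
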