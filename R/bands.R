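#' Frequency band specification
#'
#' A band is a named frequency interval in Hz. The canonical bank used for
#' differential-entropy features covers the five classical EEG rhythms:
#' Delta 1--3, Theta 4--7, Alpha 8--13, Beta 14--30 and Gamma 31--50 Hz.
#'
#' @param name band label.
#' @param lo,hi band edges in Hz, `0 < lo < hi`.
#' @return An object of class `band_spec`.
#' @examples
#' band_spec("Alpha", 8, 13)
#' @export
band_spec <- function(name, lo, hi) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.finite(lo) || !is.finite(hi) || lo <= 0 || hi <= lo)
    stop("band edges must satisfy 0 < lo < hi (got [", lo, ", ", hi, "])")
  structure(list(name = name, lo = lo, hi = hi), class = "band_spec")
}

#' @export
format.band_spec <- function(x, ...) {
  sprintf("%s [%g-%g Hz]", x$name, x$lo, x$hi)
}

#' @export
print.band_spec <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' The canonical five-band EEG bank
#'
#' @return List of five [band_spec()] objects: Delta (1--3 Hz), Theta
#'   (4--7 Hz), Alpha (8--13 Hz), Beta (14--30 Hz), Gamma (31--50 Hz).
#' @export
default_bands <- function() {
  list(
    band_spec("Delta", 1, 3),
    band_spec("Theta", 4, 7),
    band_spec("Alpha", 8, 13),
    band_spec("Beta", 14, 30),
    band_spec("Gamma", 31, 50)
  )
}

band_names <- function(bands) vapply(bands, `[[`, character(1), "name")
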