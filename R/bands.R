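# Canonical EEG frequency bands.

#' Frequency band definition
#'
#' @param name Band name.
#' @param low,high Band edges in Hz, `0 < low < high`.
#' @return An object of class `"band_def"`.
#' @export
band_def <- function(name, low, high) {
  stopifnot(is.character(name), low > 0, high > low)
  structure(list(name = name, low = low, high = high), class = "band_def")
}

#' Standard EEG bands
#'
#' The fixed band set used throughout: delta (1-4 Hz), theta (4-7 Hz),
#' alpha (8-12 Hz) and beta (13-30 Hz).
#'
#' @param names Optional subset of band names to return.
#' @return Named list of [band_def()] objects.
#' @examples
#' standard_bands()$theta
#' @export
standard_bands <- function(names = NULL) {
  all <- list(delta = band_def("delta", 1, 4),
              theta = band_def("theta", 4, 7),
              alpha = band_def("alpha", 8, 12),
              beta  = band_def("beta", 13, 30))
  if (is.null(names)) return(all)
  unknown <- setdiff(names, names(all))
  if (length(unknown)) {
    stop("unknown band(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  all[names]
}
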