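# Portable serialization of epochs and ITC maps: flat little-endian
# float64 array plus a JSON sidecar with axes and metadata.

write_array_container <- function(dir, array_data, meta) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  con <- file(file.path(dir, "data.bin"), "wb")
  writeBin(as.numeric(array_data), con, size = 8, endian = "little")
  close(con)
  meta$dim <- dim(array_data)
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(dir)
}

read_array_container <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  n <- prod(meta$dim)
  con <- file(file.path(dir, "data.bin"), "rb")
  x <- readBin(con, numeric(), n = n, size = 8, endian = "little")
  close(con)
  if (length(x) != n) stop("array container truncated: ", dir, call. = FALSE)
  dim(x) <- meta$dim
  list(data = x, meta = meta)
}

#' Serialize epochs to a portable container
#'
#' Writes the sample array as flat little-endian float64 (`data.bin`) with
#' a JSON sidecar (`meta.json`) holding dimensions, sampling rate, time
#' axis, channel labels, condition labels, event latencies and montage, so
#' any numeric environment can reload the data.
#'
#' @param epochs An [eeg_epochs()] object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_epochs <- function(epochs, dir) {
  stopifnot(inherits(epochs, "eeg_epochs"))
  meta <- list(kind = "eeg_epochs", srate = epochs$srate, time_ms = epochs$time,
               channels = epochs$channels, condition = epochs$condition,
               events = epochs$events)
  if (!is.null(epochs$montage)) {
    meta$montage <- as.data.frame(unclass(epochs$montage))
  }
  write_array_container(dir, epochs$data, meta)
}

#' @rdname write_epochs
#' @export
read_epochs <- function(dir) {
  x <- read_array_container(dir)
  m <- x$meta
  if (!identical(m$kind, "eeg_epochs")) {
    stop("container does not hold epochs: ", dir, call. = FALSE)
  }
  montage <- if (!is.null(m$montage)) {
    structure(as.data.frame(m$montage), class = c("montage", "data.frame"))
  } else NULL
  eeg_epochs(x$data, srate = m$srate, time = m$time_ms, channels = m$channels,
             condition = m$condition, events = as.data.frame(m$events),
             montage = montage)
}

#' Serialize an ITC map to a portable container
#'
#' @param map An [compute_itc()] result.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_itc <- function(map, dir) {
  stopifnot(inherits(map, "itc_map"))
  meta <- list(kind = "itc_map", freqs = map$freqs, time_ms = map$time,
               channels = map$channels, n_trials = map$n_trials,
               alpha = map$alpha, threshold = map$threshold,
               mask = as.integer(map$mask), valid = as.integer(map$valid))
  write_array_container(dir, map$itc, meta)
}

#' @rdname write_itc
#' @export
read_itc <- function(dir) {
  x <- read_array_container(dir)
  m <- x$meta
  if (!identical(m$kind, "itc_map")) {
    stop("container does not hold an ITC map: ", dir, call. = FALSE)
  }
  mask <- array(as.logical(m$mask), dim = m$dim,
                dimnames = list(m$channels, NULL, NULL))
  valid <- matrix(as.logical(m$valid), nrow = length(m$freqs))
  itc <- x$data
  dimnames(itc) <- list(m$channels, NULL, NULL)
  structure(list(itc = itc, mask = mask, threshold = m$threshold,
                 n_trials = m$n_trials, freqs = m$freqs, time = m$time_ms,
                 valid = valid, channels = m$channels, alpha = m$alpha),
            class = "itc_map")
}
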