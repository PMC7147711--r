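# 10-20 montage and the default electrode-pair set for connectivity.

#' Standard 32-channel 10-20 montage
#'
#' Channel labels and schematic 2-D head layout coordinates (nose up, unit
#' head radius) for a 32-electrode cap laid out on the international 10-20
#' system, including the frontal (F3, FZ, F4), occipital (O1, OZ, O2) and
#' temporal (T7, TP7, T8, TP8) sites used for connectivity analysis.
#'
#' @param channels Optional character vector to subset/reorder the montage.
#' @return An object of class `"montage"`: data frame with columns
#'   `channel`, `x`, `y`.
#' @examples
#' m <- montage_1020()
#' nrow(m)  # 32
#' @export
montage_1020 <- function(channels = NULL) {
  full <- data.frame(
    channel = c("FP1", "FP2", "F7", "F3", "FZ", "F4", "F8",
                "FT7", "FC3", "FCZ", "FC4", "FT8",
                "T7", "C3", "CZ", "C4", "T8",
                "TP7", "CP3", "CPZ", "CP4", "TP8",
                "P7", "P3", "PZ", "P4", "P8",
                "O1", "OZ", "O2", "A1", "A2"),
    x = c(-0.31, 0.31, -0.81, -0.42, 0.00, 0.42, 0.81,
          -0.95, -0.50, 0.00, 0.50, 0.95,
          -1.00, -0.52, 0.00, 0.52, 1.00,
          -0.95, -0.50, 0.00, 0.50, 0.95,
          -0.81, -0.42, 0.00, 0.42, 0.81,
          -0.31, 0.00, 0.31, -1.15, 1.15),
    y = c(0.95, 0.95, 0.59, 0.56, 0.52, 0.56, 0.59,
          0.31, 0.28, 0.26, 0.28, 0.31,
          0.00, 0.00, 0.00, 0.00, 0.00,
          -0.31, -0.28, -0.26, -0.28, -0.31,
          -0.59, -0.56, -0.52, -0.56, -0.59,
          -0.95, -1.00, -0.95, 0.10, 0.10),
    stringsAsFactors = FALSE
  )
  if (!is.null(channels)) {
    channels <- toupper(channels)
    missing <- setdiff(channels, full$channel)
    if (length(missing)) {
      stop("unknown montage channels: ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    full <- full[match(channels, full$channel), , drop = FALSE]
    rownames(full) <- NULL
  }
  structure(full, class = c("montage", "data.frame"))
}

#' Default electrode-pair set for connectivity
#'
#' The eleven 10-20 channel pairs spanning frontal, temporal and occipital
#' cortex used for phase-locking connectivity: F3-F4, F3-T7, T7-O1, O1-O2,
#' T8-O2, F4-T8, F4-O1, F4-O2, F3-O2, F3-O1 and T7-T8.
#'
#' @param pairs Optional two-column character matrix or list of length-2
#'   character vectors to override the default.
#' @param montage Montage used to validate channel names.
#' @return A two-column character matrix of class `"pair_set"`.
#' @export
pair_set <- function(pairs = NULL, montage = montage_1020()) {
  if (is.null(pairs)) {
    pairs <- rbind(
      c("F3", "F4"), c("F3", "T7"), c("T7", "O1"), c("O1", "O2"),
      c("T8", "O2"), c("F4", "T8"), c("F4", "O1"), c("F4", "O2"),
      c("F3", "O2"), c("F3", "O1"), c("T7", "T8")
    )
  }
  if (is.list(pairs)) pairs <- do.call(rbind, pairs)
  pairs <- matrix(toupper(as.character(pairs)), ncol = 2)
  if (any(pairs[, 1] == pairs[, 2])) {
    stop("pair set may not contain self-pairs", call. = FALSE)
  }
  unknown <- setdiff(unique(as.vector(pairs)), montage$channel)
  if (length(unknown)) {
    stop("pair set references channels not in the montage: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  colnames(pairs) <- c("ch1", "ch2")
  structure(pairs, class = c("pair_set", class(pairs)))
}

pair_labels <- function(pairs) paste(pairs[, 1], pairs[, 2], sep = "-")
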