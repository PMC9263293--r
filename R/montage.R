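#' Standard 30-channel 10-20 montage with lobe assignment
#'
#' Returns the electrode montage used throughout the package: 30 channels of
#' the international 10-20 system partitioned into five zones (frontal,
#' parietal, temporal, occipital, central). The central channels C3/Cz/C4 form
#' an explicit fifth zone: they are full network nodes but are conventionally
#' reported separately from the four classical lobes in regional summaries.
#'
#' @param labels Optional character vector of channel labels to build a
#'   montage for. Labels are matched case-insensitively against the canonical
#'   spelling; unknown labels are retained with lobe \code{"unassigned"}.
#' @return A data.frame of class \code{"montage"} with columns
#'   \code{channel} and \code{lobe}, one row per channel, in channel order.
#' @examples
#' m <- montage_1020()
#' table(m$lobe)
#' @export
montage_1020 <- function(labels = NULL) {
  lobes <- list(
    frontal   = c("FP1", "FP2", "F7", "F8", "F3", "F4", "FZ", "FC3", "FCz", "FC4"),
    parietal  = c("CP3", "CPz", "CP4", "P3", "Pz", "P4"),
    temporal  = c("FT7", "FT8", "T3", "T4", "TP7", "TP8", "T5", "T6"),
    occipital = c("O1", "OZ", "O2"),
    central   = c("C3", "Cz", "C4")
  )
  canon <- unlist(lobes, use.names = FALSE)
  lobe_of <- rep(names(lobes), vapply(lobes, length, integer(1)))
  # anatomically ordered default layout (front to back)
  default_order <- c("FP1", "FP2", "F7", "F3", "FZ", "F4", "F8",
                     "FC3", "FCz", "FC4", "FT7", "FT8",
                     "T3", "C3", "Cz", "C4", "T4",
                     "TP7", "CP3", "CPz", "CP4", "TP8",
                     "T5", "P3", "Pz", "P4", "T6",
                     "O1", "OZ", "O2")
  if (is.null(labels)) labels <- default_order
  idx <- match(toupper(labels), toupper(canon))
  out <- data.frame(
    channel = ifelse(is.na(idx), labels, canon[idx]),
    lobe = ifelse(is.na(idx), "unassigned", lobe_of[idx]),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(out$channel)) stop("duplicate channel labels in montage")
  class(out) <- c("montage", "data.frame")
  out
}

#' Normalize channel labels to canonical 10-20 spelling
#'
#' @param labels character vector of raw labels.
#' @param warn emit a warning listing labels that are not part of the
#'   canonical 30-channel montage.
#' @return character vector of normalized labels (unknown labels unchanged).
#' @export
normalize_labels <- function(labels, warn = TRUE) {
  m <- montage_1020(labels)
  if (warn && any(m$lobe == "unassigned")) {
    warning("unknown channel label(s): ",
            paste(m$channel[m$lobe == "unassigned"], collapse = ", "),
            "; retained with lobe 'unassigned'")
  }
  m$channel
}
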