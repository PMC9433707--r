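#' Load an electrode montage
#'
#' Reads a montage CSV (`label,x,y`: 2-D head-plane coordinates on a
#' unit-circle head, nose up). The packaged default is the 64-channel
#' extended 10-20 layout used by BioSemi 64-electrode caps.
#'
#' @param path CSV path; default is the packaged 64-channel layout.
#' @return A data.frame with columns `label`, `x`, `y`, class `eeg_montage`.
#' @export
load_montage <- function(path = system.file("extdata", "biosemi64_montage.csv",
                                            package = "csepnet")) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("label", "x", "y") %in% names(m))) {
    stopf("montage file %s must have columns label, x, y", path)
  }
  if (anyDuplicated(m$label)) stopf("montage labels must be unique")
  r <- sqrt(m$x^2 + m$y^2)
  if (any(r > 1.2)) {
    stopf("montage coordinate %s is outside the head (radius %.2f > 1.2)",
          m$label[which.max(r)], max(r))
  }
  class(m) <- c("eeg_montage", "data.frame")
  m
}

#' Channel labels of the packaged 64-channel montage, in row order
#' @return Character vector of 64 labels.
#' @export
montage_labels <- function() load_montage()$label
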