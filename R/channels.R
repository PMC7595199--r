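#' Canonical headband electrode montage
#'
#' The portable headband used throughout this package carries four dry EEG
#' electrodes: two over the temporal-posterior scalp (TP9 left, TP10 right,
#' the ear-clip electrodes) and two frontal (AF7 left, AF8 right).  Vendor
#' exports sometimes label these with non-standard shorthand (A7/A8 for the
#' frontal pair, T9/T10 for the posterior pair); [canonical_channel()] maps
#' those onto the 10-20 style names used everywhere in this package.
#'
#' @return A data frame with columns `name`, `hemisphere`
#'   (`"left"`/`"right"`) and `region` (`"temporal-posterior"`/`"frontal"`),
#'   one row per canonical electrode.
#' @examples
#' muse_channels()
#' @export
muse_channels <- function() {
  data.frame(
    name       = c("TP9", "AF7", "AF8", "TP10"),
    hemisphere = c("left", "left", "right", "right"),
    region     = c("temporal-posterior", "frontal", "frontal",
                   "temporal-posterior"),
    stringsAsFactors = FALSE
  )
}

#' Canonicalise an electrode label
#'
#' @param name Character vector of electrode labels as found in a session
#'   file (case-insensitive; `A7`, `A8`, `T9`, `T10` and `RAW_*` vendor
#'   prefixes are accepted aliases).
#' @return The canonical labels (`TP9`, `AF7`, `AF8`, `TP10`); unknown
#'   labels are returned as `NA`.
#' @export
canonical_channel <- function(name) {
  key <- toupper(sub("^RAW_", "", trimws(name)))
  map <- c(TP9 = "TP9", TP10 = "TP10", AF7 = "AF7", AF8 = "AF8",
           A7 = "AF7", A8 = "AF8", T9 = "TP9", T10 = "TP10")
  out <- unname(map[key])
  out
}

channel_spec <- function(names) {
  canon <- muse_channels()
  idx <- match(names, canon$name)
  if (anyNA(idx))
    abort_format(sprintf("unknown channel label(s): %s",
                         paste(names[is.na(idx)], collapse = ", ")))
  if (anyDuplicated(names))
    abort_format("duplicate channel labels in recording")
  canon[idx, , drop = FALSE]
}
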