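#' Default prefrontal channel layout
#'
#' Fifteen channels (Ch01..Ch15) arranged over the forehead, each formed by a
#' source-detector pair at a fixed inter-optode separation, measured at two
#' near-infrared wavelengths. Each channel belongs to exactly one of seven
#' prefrontal regions of interest (see [roi_map()]).
#'
#' @param distance_cm Source-detector separation in cm (default 3).
#' @param wavelengths_nm Nominal wavelength pair in nm (default 780, 850).
#' @return A data frame with one row per channel: `channel`, `source`,
#'   `detector`, `distance_cm`, `roi`, `region`.
#' @export
channel_layout <- function(distance_cm = 3, wavelengths_nm = c(780, 850)) {
  assert_scalar_num(distance_cm, "distance_cm", lower = 1e-9)
  if (length(wavelengths_nm) != 2L) stopf("`wavelengths_nm` must have length 2")
  map <- roi_map()
  roi_of <- stats::setNames(rep(names(map$channels), lengths(map$channels)),
                            unlist(map$channels))
  ch <- sprintf("Ch%02d", 1:15)
  out <- data.frame(
    channel = ch,
    source = sprintf("S%d", ceiling(1:15 / 2)),
    detector = sprintf("D%d", 1:15),
    distance_cm = distance_cm,
    roi = roi_of[ch],
    region = map$regions[roi_of[ch]],
    row.names = NULL, stringsAsFactors = FALSE
  )
  attr(out, "wavelengths_nm") <- wavelengths_nm
  class(out) <- c("channel_layout", "data.frame")
  out
}

#' Region-of-interest partition of the 15-channel montage
#'
#' The seven prefrontal ROIs: ROI1 lateral right (Ch01, Ch02), ROI2 upper
#' right (Ch03, Ch05, Ch06), ROI3 lower right (Ch04, Ch07), ROI4 center
#' (Ch08; the seed region, adjacent to the medial prefrontal cortex), ROI5
#' upper left (Ch09, Ch11, Ch12), ROI6 lower left (Ch10, Ch13), ROI7 lateral
#' left (Ch14, Ch15). The partition is disjoint and exhaustive.
#'
#' @return A list with `channels` (named list ROI -> channel ids), `regions`
#'   (named character vector of anatomical labels), `seed` (the seed ROI id),
#'   and `seed_targets` (target ROI ids in seed-connection order S1..S6).
#' @export
roi_map <- function() {
  channels <- list(
    ROI1 = c("Ch01", "Ch02"),
    ROI2 = c("Ch03", "Ch05", "Ch06"),
    ROI3 = c("Ch04", "Ch07"),
    ROI4 = "Ch08",
    ROI5 = c("Ch09", "Ch11", "Ch12"),
    ROI6 = c("Ch10", "Ch13"),
    ROI7 = c("Ch14", "Ch15")
  )
  regions <- c(ROI1 = "Lateral right", ROI2 = "Upper right", ROI3 = "Lower right",
               ROI4 = "Center", ROI5 = "Upper left", ROI6 = "Lower left",
               ROI7 = "Lateral left")
  list(channels = channels, regions = regions, seed = "ROI4",
       seed_targets = c("ROI1", "ROI2", "ROI3", "ROI5", "ROI6", "ROI7"))
}

validate_roi_map <- function(map, channels) {
  all_ch <- unlist(map$channels, use.names = FALSE)
  if (anyDuplicated(all_ch)) stopf("ROI map is not disjoint")
  if (!setequal(all_ch, channels)) stopf("ROI map does not cover the channel set exactly")
  invisible(map)
}
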