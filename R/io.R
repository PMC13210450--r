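# Delimited (tab-separated) interchange formats. A recording is written as
# two files: <path> with a time column plus one column per trace, and
# <path>.markers with (time, label). Raw intensity traces are named
# <channel>_<wavelength>.

#' Write a recording to delimited files
#'
#' @param x A [hemo_series()] or [raw_intensity()] object.
#' @param path Output file path; markers go to `<path>.markers` when present.
#' @return `path`, invisibly.
#' @export
write_recording <- function(x, path) {
  if (inherits(x, "hemo_series")) {
    tab <- data.frame(time = hemo_times(x), x$hbo, check.names = FALSE)
    names(tab)[-1] <- paste0(x$channels, "_HbO")
    if (!is.null(x$hbr)) {
      hbr <- as.data.frame(x$hbr)
      names(hbr) <- paste0(x$channels, "_HbR")
      tab <- cbind(tab, hbr)
    }
    markers <- x$markers
  } else if (inherits(x, "raw_intensity")) {
    n <- dim(x$intensity)[1]
    t <- (seq_len(n) - 1) / x$fs
    cols <- list(time = t)
    for (j in seq_along(x$channels)) {
      for (w in 1:2) {
        cols[[sprintf("%s_%d", x$channels[j], x$wavelengths_nm[w])]] <- x$intensity[, j, w]
      }
    }
    tab <- as.data.frame(cols, check.names = FALSE)
    markers <- x$markers
    utils::write.table(data.frame(channel = x$channels, x$baseline, check.names = FALSE),
                       paste0(path, ".baseline"), sep = "\t", row.names = FALSE, quote = FALSE)
  } else {
    stopf("unsupported object of class %s", paste(class(x), collapse = "/"))
  }
  utils::write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  if (!is.null(markers)) {
    utils::write.table(markers, paste0(path, ".markers"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Read a recording from delimited files
#'
#' Reads a table written by [write_recording()] (or any delimited table with
#' a `time` column and `<channel>_HbO` / `<channel>_<wavelength>` columns)
#' back into the matching container. Only the delimited format is supported.
#'
#' @param path File path.
#' @param format Input format; `"delimited"` is the supported value.
#' @param what `"hemo"` for concentration series, `"intensity"` for raw
#'   dual-wavelength intensities.
#' @return A [hemo_series()] or [raw_intensity()].
#' @export
read_recording <- function(path, format = "delimited", what = c("hemo", "intensity")) {
  format <- match.arg(format, "delimited")
  what <- match.arg(what)
  if (!file.exists(path)) stopf("file not found: %s", path)
  tab <- utils::read.delim(path, check.names = FALSE)
  if (!"time" %in% names(tab)) stopf("malformed recording: missing `time` column in %s", path)
  if (nrow(tab) < 2) stopf("malformed recording: fewer than 2 samples in %s", path)
  t <- tab$time
  dt <- diff(t)
  if (any(!is.finite(dt)) || any(dt <= 0) || (max(dt) - min(dt)) > 1e-6) {
    stopf("malformed recording: `time` column is not a regular grid in %s", path)
  }
  fs <- 1 / stats::median(dt)
  markers <- NULL
  mpath <- paste0(path, ".markers")
  if (file.exists(mpath)) markers <- utils::read.delim(mpath, stringsAsFactors = FALSE)

  if (what == "hemo") {
    hbo_cols <- grep("_HbO$", names(tab), value = TRUE)
    if (!length(hbo_cols)) stopf("malformed recording: no `_HbO` columns in %s", path)
    channels <- sub("_HbO$", "", hbo_cols)
    hbr_cols <- paste0(channels, "_HbR")
    hbr <- if (all(hbr_cols %in% names(tab))) as.matrix(tab[hbr_cols]) else NULL
    hemo_series(as.matrix(tab[hbo_cols]), fs = fs, channels = channels,
                hbr = hbr, markers = markers, start = t[1])
  } else {
    trace_cols <- setdiff(names(tab), "time")
    parts <- regmatches(trace_cols, regexec("^(.*)_(\\d+)$", trace_cols))
    if (any(lengths(parts) != 3)) stopf("malformed recording: intensity columns must be <channel>_<wavelength> in %s", path)
    channels <- unique(vapply(parts, `[`, character(1), 2))
    wavelengths <- sort(unique(as.numeric(vapply(parts, `[`, character(1), 3))))
    if (length(wavelengths) != 2) stopf("malformed recording: expected 2 wavelengths, found %d", length(wavelengths))
    arr <- array(NA_real_, c(nrow(tab), length(channels), 2),
                 dimnames = list(NULL, channels, wavelengths))
    for (j in seq_along(channels)) {
      for (w in 1:2) {
        cn <- sprintf("%s_%d", channels[j], wavelengths[w])
        if (!cn %in% names(tab)) stopf("malformed recording: missing column %s", cn)
        arr[, j, w] <- tab[[cn]]
      }
    }
    bpath <- paste0(path, ".baseline")
    baseline <- if (file.exists(bpath)) {
      as.matrix(utils::read.delim(bpath, row.names = 1))
    } else {
      matrix(1, length(channels), 2)
    }
    raw_intensity(arr, fs = fs, baseline = baseline, wavelengths_nm = wavelengths,
                  channels = channels, markers = markers)
  }
}

#' Write the events table of a schedule
#'
#' One row per stimulus screen: `onset_s`, `duration_s`, `condition`,
#' `screen_index`.
#'
#' @param schedule A [generate_paradigm()] schedule.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_events <- function(schedule, path) {
  ev <- data.frame(onset_s = schedule$screens$onset,
                   duration_s = schedule$screens$duration,
                   condition = schedule$screens$condition,
                   screen_index = schedule$screens$screen)
  utils::write.table(ev, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an events table
#' @param path Path written by [write_events()].
#' @return Data frame of events.
#' @export
read_events <- function(path) utils::read.delim(path, stringsAsFactors = FALSE)

#' Write / read a behavioral selection log
#' @param records Selection log data frame.
#' @param path File path.
#' @return `path` (write) or the data frame (read).
#' @export
write_behavior_log <- function(records, path) {
  utils::write.table(records, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_behavior_log
#' @export
read_behavior_log <- function(path) utils::read.delim(path, stringsAsFactors = FALSE)

#' Write a connectivity matrix as a labeled square table
#' @param M A `conn_matrix`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_conn_matrix <- function(M, path) {
  utils::write.table(as.data.frame(unclass(M)), path, sep = "\t",
                     row.names = TRUE, col.names = NA, quote = FALSE)
  invisible(path)
}
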