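#' Scan filter descriptor
#'
#' Identifies an acquisition channel of an MS2I run: the mass analyzer,
#' the MS level and, for MS2 scans, the precursor isolation window and
#' activation. Spectra sharing a filter are assembled into one image
#' channel by [assign_pixels()].
#'
#' @param analyzer `"FT"` (orbitrap/FT-ICR full scans) or `"IT"` (ion-trap
#'   MS2 scans).
#' @param ms_level integer MS level (>= 1).
#' @param isolation_center precursor isolation window center (Th); required
#'   when `ms_level >= 2`, must be absent for MS1.
#' @param isolation_width full isolation width (Da), e.g. `0.7`.
#' @param activation `"HCD"`, `"CID"` or `"none"`.
#' @param list_index 0-based inclusion-list index in `[0, N)`, or `NA` when
#'   not (yet) assigned. [assign_pixels()] derives it from the pixel column.
#' @return An object of class `scan_filter`.
#' @examples
#' scan_filter("FT", 1)
#' scan_filter("IT", 2, isolation_center = 808.6, isolation_width = 0.7,
#'             activation = "HCD")
#' @export
scan_filter <- function(analyzer = c("FT", "IT"), ms_level = 1L,
                        isolation_center = NULL, isolation_width = NULL,
                        activation = c("none", "HCD", "CID"),
                        list_index = NA_integer_) {
  analyzer <- match.arg(analyzer)
  activation <- match.arg(activation)
  ms_level <- as.integer(ms_level)
  if (ms_level < 1L) stop("ms_level must be >= 1")
  if (ms_level == 1L) {
    if (!is.null(isolation_center) || !is.null(isolation_width))
      stop("MS1 scan filters carry no isolation window")
    isolation_center <- NA_real_
    isolation_width <- NA_real_
  } else {
    if (is.null(isolation_center) || is.null(isolation_width) ||
        !is.finite(isolation_center) || !is.finite(isolation_width) ||
        isolation_center <= 0 || isolation_width <= 0)
      stop("MS2 scan filters require isolation_center > 0 and isolation_width > 0")
  }
  structure(
    list(analyzer = analyzer, ms_level = ms_level,
         isolation_center = as.numeric(isolation_center),
         isolation_width = as.numeric(isolation_width),
         activation = activation, list_index = as.integer(list_index)),
    class = "scan_filter")
}

#' Canonical string key of a scan filter
#'
#' Used as the channel name inside an [assign_pixels()] dataset. Two filters
#' with the same key address the same channel.
#'
#' @param filter a [scan_filter()].
#' @return A single string.
#' @export
filter_key <- function(filter) {
  stopifnot(inherits(filter, "scan_filter"))
  if (filter$ms_level == 1L) return(sprintf("%s MS1", filter$analyzer))
  li <- if (is.na(filter$list_index)) "" else sprintf(" L%d", filter$list_index)
  sprintf("%s MS2 %.4f/%.2f %s%s", filter$analyzer, filter$isolation_center,
          filter$isolation_width, filter$activation, li)
}

#' @export
print.scan_filter <- function(x, ...) {
  cat("<scan_filter> ", filter_key(x), "\n", sep = "")
  invisible(x)
}

#' @export
format.scan_filter <- function(x, ...) filter_key(x)

# peak list = two-column numeric matrix (mz, intensity); mz strictly
# increasing, intensities nonnegative
validate_peaks <- function(peaks, where = "peak list") {
  if (!is.matrix(peaks) || ncol(peaks) != 2L || !is.numeric(peaks))
    stop(where, ": peaks must be a numeric matrix with columns mz, intensity")
  if (nrow(peaks) > 0L) {
    if (any(diff(peaks[, 1L]) <= 0))
      stop(where, ": m/z values must be strictly increasing")
    if (any(peaks[, 2L] < 0))
      stop(where, ": intensities must be nonnegative")
  }
  invisible(peaks)
}

empty_peaks <- function() {
  matrix(numeric(0), ncol = 2L, dimnames = list(NULL, c("mz", "intensity")))
}

# sort a raw (mz, intensity) matrix and merge exactly coincident m/z
as_peaklist <- function(mz, intensity) {
  if (length(mz) == 0L) return(empty_peaks())
  o <- order(mz)
  mz <- mz[o]; intensity <- intensity[o]
  if (anyDuplicated(mz)) {
    intensity <- as.numeric(tapply(intensity, factor(mz, levels = unique(mz)), sum))
    mz <- unique(mz)
  }
  cbind(mz = mz, intensity = intensity)
}

new_spectrum_record <- function(index, filter, peaks, retention_time) {
  structure(list(index = as.integer(index), filter = filter,
                 peaks = peaks, retention_time = as.numeric(retention_time)),
            class = "spectrum_record")
}

#' @export
print.spectrum_record <- function(x, ...) {
  cat(sprintf("<spectrum_record> #%d %s rt=%.2fs peaks=%d\n",
              x$index, filter_key(x$filter), x$retention_time, nrow(x$peaks)))
  invisible(x)
}
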