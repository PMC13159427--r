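#' Parallel image acquisition configuration
#'
#' Timing and geometry of a PIA experiment: one high-resolution FT full
#' scan acquired per pixel in parallel with `n_ms2_per_ft` targeted
#' ion-trap MS2 scans, cycling through `n_lists` inclusion lists along the
#' x direction. With the default Orbitrap settings (1024 ms transient,
#' 5 ms accumulation) more than 99.5 % of the incoming ion current would
#' otherwise go unused; the parallel ion-trap scans recover it.
#'
#' @param ft_scan_time_ms duration of one FT transient (ms).
#' @param ft_accumulation_ms ion accumulation time per FT scan (ms).
#' @param n_lists number of inclusion lists N.
#' @param windows_per_list isolation windows per inclusion list.
#' @param n_ms2_per_ft MS2 scans acquired during one FT scan (defaults to
#'   `windows_per_list`: each window of the pixel's list scanned once).
#' @param isolation_width_da full isolation width (Da).
#' @param ft_pixel_x_um,ft_pixel_y_um FT pixel size (micrometres).
#' @param inclusion_lists optional list of `n_lists` numeric vectors of
#'   window centers (Th), each of length `windows_per_list`; consumed by
#'   [build_schedule()] and the synthetic writer.
#' @return An object of class `acquisition_config`.
#' @examples
#' acquisition_config()          # the 4 x 27-window configuration
#' @export
acquisition_config <- function(ft_scan_time_ms = 1024, ft_accumulation_ms = 5,
                               n_lists = 4L, windows_per_list = 27L,
                               n_ms2_per_ft = windows_per_list,
                               isolation_width_da = 0.7,
                               ft_pixel_x_um = 20, ft_pixel_y_um = 50,
                               inclusion_lists = NULL) {
  vals <- c(ft_scan_time_ms, ft_accumulation_ms, isolation_width_da,
            ft_pixel_x_um, ft_pixel_y_um)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all timing and geometry parameters must be positive")
  n_lists <- as.integer(n_lists)
  windows_per_list <- as.integer(windows_per_list)
  n_ms2_per_ft <- as.integer(n_ms2_per_ft)
  if (n_lists < 1L || windows_per_list < 1L || n_ms2_per_ft < 1L)
    stop("n_lists, windows_per_list and n_ms2_per_ft must be >= 1")
  if (!is.null(inclusion_lists)) {
    if (length(inclusion_lists) != n_lists ||
        any(lengths(inclusion_lists) != windows_per_list))
      stop("inclusion_lists must hold n_lists vectors of windows_per_list centers")
  }
  structure(list(ft_scan_time_ms = ft_scan_time_ms,
                 ft_accumulation_ms = ft_accumulation_ms,
                 n_lists = n_lists, windows_per_list = windows_per_list,
                 n_ms2_per_ft = n_ms2_per_ft,
                 isolation_width_da = isolation_width_da,
                 ft_pixel_x_um = ft_pixel_x_um,
                 ft_pixel_y_um = ft_pixel_y_um,
                 inclusion_lists = inclusion_lists),
            class = "acquisition_config")
}

#' FT ion utilization under parallel acquisition
#'
#' Fraction of the continuously arriving ion current actually accumulated
#' for the FT scan, `accumulation / scan time`; the complement is the
#' fraction the parallel ion-trap MS2 scans can exploit.
#'
#' @param config an [acquisition_config()].
#' @return List with `used` and `unused` fractions (summing to 1).
#' @examples
#' ion_utilization(acquisition_config(1024, 5))$unused   # > 0.995
#' @export
ion_utilization <- function(config) {
  stopifnot(inherits(config, "acquisition_config"))
  if (config$ft_accumulation_ms > config$ft_scan_time_ms)
    stop("accumulation time cannot exceed the scan time")
  used <- config$ft_accumulation_ms / config$ft_scan_time_ms
  list(used = used, unused = 1 - used)
}

#' Total precursor-window coverage
#'
#' @param config an [acquisition_config()].
#' @return `n_lists * windows_per_list`, the number of distinct isolation
#'   windows covered per full list cycle.
#' @examples
#' pia_coverage(acquisition_config(n_lists = 4, windows_per_list = 27)) # 108
#' @export
pia_coverage <- function(config) {
  stopifnot(inherits(config, "acquisition_config"))
  config$n_lists * config$windows_per_list
}

#' MS2 pixel geometry
#'
#' Cycling N inclusion lists along x means each list revisits every Nth FT
#' pixel, so the MS2 pixel size in x grows by the factor N; y is unchanged.
#'
#' @param config an [acquisition_config()].
#' @return Named numeric vector `c(x = ..., y = ...)` in micrometres.
#' @examples
#' ms2_geometry(acquisition_config(ft_pixel_x_um = 20, n_lists = 4)) # 80, 50
#' @export
ms2_geometry <- function(config) {
  stopifnot(inherits(config, "acquisition_config"))
  c(x = config$ft_pixel_x_um * config$n_lists, y = config$ft_pixel_y_um)
}

#' Duty-cycle and geometry report
#'
#' @param config an [acquisition_config()].
#' @return List of class `duty_cycle_report`: FT ion utilization and unused
#'   fraction, total window coverage, MS2 x pixel size, and the number of
#'   MS2 spectra acquired over one full N-pixel list cycle.
#' @export
duty_cycle_report <- function(config) {
  u <- ion_utilization(config)
  structure(list(ft_ion_utilization = u$used, ft_ion_unused = u$unused,
                 total_windows = pia_coverage(config),
                 ms2_pixel_x_um = unname(ms2_geometry(config)["x"]),
                 ms2_spectra_per_pixel_cycle =
                   config$n_ms2_per_ft * config$n_lists),
            class = "duty_cycle_report")
}

#' @export
print.duty_cycle_report <- function(x, ...) {
  cat(sprintf(
    paste0("<duty_cycle_report>\n  FT ion utilization: %.3f%% (%.3f%% unused)\n",
           "  windows covered: %d\n  MS2 x pixel: %g um\n",
           "  MS2 spectra per N-pixel cycle: %d\n"),
    100 * x$ft_ion_utilization, 100 * x$ft_ion_unused, x$total_windows,
    x$ms2_pixel_x_um, x$ms2_spectra_per_pixel_cycle))
  invisible(x)
}

#' Build the per-pixel scan schedule
#'
#' Row-major traversal of the grid; pixel (r, c) uses inclusion list
#' `(c - 1) mod N` and acquires one FT scan plus that list's windows in
#' order. Over any N consecutive x positions every window of every list is
#' scheduled exactly once.
#'
#' @param config an [acquisition_config()]; if `inclusion_lists` is unset,
#'   windows are labelled by ordinal only (`window_mz` = NA).
#' @param grid a [pixel_grid()] with matching `n_lists`.
#' @return Data frame with one row per scan: `row`, `col` (FT pixel,
#'   1-based), `list_index` (0-based), `scan_type` (`"FT"`/`"MS2"`),
#'   `window_ordinal` (1-based within the list, NA for FT) and `window_mz`.
#' @export
build_schedule <- function(config, grid) {
  stopifnot(inherits(config, "acquisition_config"), inherits(grid, "pixel_grid"))
  if (grid$n_lists != config$n_lists)
    stop("grid and config disagree on the number of inclusion lists")
  N <- config$n_lists
  W <- config$windows_per_list
  per_pixel <- 1L + W
  npix <- grid$n_lines * grid$pixels_per_line
  rows <- rep(seq_len(grid$n_lines), each = grid$pixels_per_line * per_pixel)
  cols <- rep(rep(seq_len(grid$pixels_per_line), each = per_pixel),
              times = grid$n_lines)
  li <- (cols - 1L) %% N
  ord <- rep(c(NA_integer_, seq_len(W)), times = npix)
  type <- rep(c("FT", rep("MS2", W)), times = npix)
  mz <- rep(NA_real_, length(ord))
  if (!is.null(config$inclusion_lists)) {
    sel <- type == "MS2"
    mz[sel] <- mapply(function(l, o) config$inclusion_lists[[l + 1L]][o],
                      li[sel], ord[sel])
  }
  data.frame(row = rows, col = cols, list_index = li, scan_type = type,
             window_ordinal = ord, window_mz = mz)
}
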