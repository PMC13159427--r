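#' Pixel grid geometry of an MS2I run
#'
#' Describes the raster: scan lines (rows, y) by pixels per line (columns,
#' x), scanned row-major starting at pixel (1,1). Under parallel image
#' acquisition with `n_lists` inclusion lists the MS2 channels are
#' downsampled N-fold along x, so their x pixel size is
#' `ft_pixel_x_um * n_lists`.
#'
#' @param n_lines number of scan lines (rows).
#' @param pixels_per_line number of FT pixels per line (columns).
#' @param n_lists number of inclusion lists N (>= 1).
#' @param ft_pixel_x_um,ft_pixel_y_um FT pixel size in micrometres.
#' @return An object of class `pixel_grid` with derived fields
#'   `ms2_pixels_per_line` (`floor(pixels_per_line / n_lists)`, the number of
#'   complete list cycles per line) and `ms2_pixel_x_um`.
#' @examples
#' pixel_grid(10, 108, n_lists = 4)
#' @export
pixel_grid <- function(n_lines, pixels_per_line, n_lists = 1L,
                       ft_pixel_x_um = 20, ft_pixel_y_um = 50) {
  n_lines <- as.integer(n_lines)
  pixels_per_line <- as.integer(pixels_per_line)
  n_lists <- as.integer(n_lists)
  if (n_lines < 1L || pixels_per_line < 1L || n_lists < 1L)
    stop("all grid counts must be >= 1")
  if (ft_pixel_x_um <= 0 || ft_pixel_y_um <= 0)
    stop("pixel sizes must be positive")
  structure(
    list(n_lines = n_lines, pixels_per_line = pixels_per_line,
         n_lists = n_lists,
         ms2_pixels_per_line = pixels_per_line %/% n_lists,
         ft_pixel_x_um = as.numeric(ft_pixel_x_um),
         ft_pixel_y_um = as.numeric(ft_pixel_y_um),
         ms2_pixel_x_um = as.numeric(ft_pixel_x_um) * n_lists),
    class = "pixel_grid")
}

#' @export
print.pixel_grid <- function(x, ...) {
  cat(sprintf(
    "<pixel_grid> %d lines x %d pixels, N=%d lists; FT %gx%g um, MS2 %gx%g um\n",
    x$n_lines, x$pixels_per_line, x$n_lists,
    x$ft_pixel_x_um, x$ft_pixel_y_um, x$ms2_pixel_x_um, x$ft_pixel_y_um))
  invisible(x)
}

#' Read an mzML run into spectrum records
#'
#' Reads a centroided mzML file (plain or indexed) and returns one record
#' per spectrum in acquisition order. MS2 records carry the precursor
#' isolation window center and width read from the precursor element; an
#' MS2 spectrum without isolation metadata is a hard error. Profile-mode
#' spectra are rejected: this package operates on centroid data only.
#'
#' The mass analyzer (`FT`/`IT`) and activation (`HCD`/`CID`) are parsed
#' from the Thermo-style filter string when present; otherwise MS1 scans
#' default to `FT` and MS2 scans to `IT`, the PIA configuration.
#'
#' @param path path to an mzML file.
#' @return A list of `spectrum_record` objects (0-based `index`, a
#'   [scan_filter()], a peak matrix, and the retention time in seconds).
#' @seealso [assign_pixels()] to arrange the records on a [pixel_grid()].
#' @export
read_mzml <- function(path) {
  if (!file.exists(path)) stop("mzML file not found: ", path)
  fh <- mzR::openMSfile(path)
  on.exit(mzR::close(fh), add = TRUE)
  hd <- mzR::header(fh)
  n <- nrow(hd)
  if (n == 0L) return(list())
  if (any(!is.na(hd$centroided) & !hd$centroided))
    stop("profile-mode spectra are unsupported; centroid the data first ",
         "(first profile spectrum index ",
         which(!is.na(hd$centroided) & !hd$centroided)[1L] - 1L, ")")
  pk <- mzR::peaks(fh)
  if (n == 1L && is.matrix(pk)) pk <- list(pk)
  fs <- if ("filterString" %in% names(hd)) as.character(hd$filterString)
        else rep(NA_character_, n)
  records <- vector("list", n)
  for (i in seq_len(n)) {
    lvl <- hd$msLevel[i]
    analyzer <- if (!is.na(fs[i]) && grepl("^ITMS", fs[i])) "IT"
                else if (!is.na(fs[i]) && grepl("^FTMS", fs[i])) "FT"
                else if (lvl == 1L) "FT" else "IT"
    activation <- if (!is.na(fs[i]) && grepl("@hcd", fs[i], ignore.case = TRUE)) "HCD"
                  else if (!is.na(fs[i]) && grepl("@cid", fs[i], ignore.case = TRUE)) "CID"
                  else "none"
    if (lvl >= 2L) {
      ctr <- hd$isolationWindowTargetMZ[i]
      if (is.na(ctr)) ctr <- hd$precursorMZ[i]
      wid <- hd$isolationWindowLowerOffset[i] + hd$isolationWindowUpperOffset[i]
      if (is.na(ctr) || ctr <= 0)
        stop("MS2 spectrum at index ", i - 1L,
             " lacks precursor isolation metadata")
      if (is.na(wid) || wid <= 0)
        stop("MS2 spectrum at index ", i - 1L,
             " lacks an isolation window width")
      filt <- scan_filter(analyzer, lvl, isolation_center = ctr,
                          isolation_width = wid, activation = activation)
    } else {
      filt <- scan_filter(analyzer, 1L)
    }
    m <- pk[[i]]
    if (nrow(m) == 0L) m <- empty_peaks() else colnames(m) <- c("mz", "intensity")
    validate_peaks(m, where = sprintf("spectrum %d", i - 1L))
    records[[i]] <- new_spectrum_record(i - 1L, filt, m, hd$retentionTime[i])
  }
  records
}

#' Arrange spectrum records on the pixel grid
#'
#' Partitions an acquisition-ordered record stream into channels, one per
#' scan filter, and places each spectrum at its pixel. Within a line the
#' repeating unit is one FT scan followed by the parallel MS2 scans of that
#' pixel's inclusion list; lists cycle along x, so pixel column `c`
#' (1-based) uses list `(c - 1) mod N`. Each MS2 filter's channel is the
#' N-fold x-downsampled grid: its list occupies FT columns
#' `list_index + 1, list_index + 1 + N, ...`, and trailing pixels a list
#' never visits are masked invalid.
#'
#' @param records list of `spectrum_record`s in acquisition order (from
#'   [read_mzml()]).
#' @param grid a [pixel_grid()].
#' @param line_breaks 1-based indices into `records` marking the first
#'   record of each scan line; the first element must be 1. Taken from the
#'   acquisition config (or the synthetic writer) rather than inferred from
#'   retention-time gaps, so pixel assignment is deterministic.
#' @return An object of class `msi_dataset`: the grid, a named list of
#'   channels (each with its `scan_filter`, a row x column list-matrix of
#'   spectra and a logical validity mask), and provenance.
#' @export
assign_pixels <- function(records, grid, line_breaks) {
  stopifnot(inherits(grid, "pixel_grid"))
  n <- length(records)
  line_breaks <- as.integer(line_breaks)
  if (length(line_breaks) != grid$n_lines || line_breaks[1L] != 1L)
    stop("line_breaks must give one starting record index per line, first = 1")
  if (is.unsorted(line_breaks, strictly = TRUE) || any(line_breaks > n))
    stop("line_breaks must be strictly increasing record indices")
  N <- grid$n_lists
  cols <- grid$pixels_per_line
  w2 <- as.integer(ceiling(cols / N))  # MS2 channel width incl. partial cycle
  ends <- c(line_breaks[-1L] - 1L, n)

  channels <- list()
  get_channel <- function(key, filt, width) {
    if (is.null(channels[[key]])) {
      channels[[key]] <<- list(
        filter = filt,
        spectra = matrix(vector("list", grid$n_lines * width),
                         nrow = grid$n_lines, ncol = width),
        valid = matrix(FALSE, grid$n_lines, width))
    }
    key
  }

  for (r in seq_len(grid$n_lines)) {
    idx <- seq(line_breaks[r], ends[r])
    lvls <- vapply(records[idx], function(s) s$filter$ms_level, integer(1))
    starts <- which(lvls == 1L)
    if (length(starts) != cols)
      stop(sprintf(
        "grid mismatch on line %d: expected %d FT pixels, found %d",
        r, cols, length(starts)))
    bend <- c(starts[-1L] - 1L, length(idx))
    for (ci in seq_along(starts)) {
      li <- (ci - 1L) %% N             # inclusion list for this pixel
      c2 <- (ci - 1L) %/% N + 1L       # MS2 channel column
      block <- idx[starts[ci]:bend[ci]]
      ft <- records[[block[1L]]]
      key <- get_channel(filter_key(ft$filter), ft$filter, cols)
      channels[[key]]$spectra[[r, ci]] <- ft
      channels[[key]]$valid[r, ci] <- TRUE
      for (b in block[-1L]) {
        sp <- records[[b]]
        filt <- sp$filter
        filt$list_index <- li
        key <- get_channel(filter_key(filt), filt, w2)
        if (channels[[key]]$valid[r, c2])
          stop(sprintf(
            "duplicate spectrum for filter '%s' at pixel (%d,%d)",
            filter_key(filt), r, c2))
        channels[[key]]$spectra[[r, c2]] <- sp
        channels[[key]]$valid[r, c2] <- TRUE
      }
    }
  }
  structure(list(grid = grid, channels = channels,
                 provenance = attr(records, "source")),
            class = "msi_dataset")
}

#' @export
print.msi_dataset <- function(x, ...) {
  cat(sprintf("<msi_dataset> %d x %d grid, %d channels\n",
              x$grid$n_lines, x$grid$pixels_per_line, length(x$channels)))
  for (k in names(x$channels))
    cat(sprintf("  %-40s %d valid pixels\n", k, sum(x$channels[[k]]$valid)))
  invisible(x)
}

#' List the channels of a dataset
#'
#' @param dataset an `msi_dataset` from [assign_pixels()].
#' @return Character vector of channel keys (see [filter_key()]).
#' @export
channel_keys <- function(dataset) {
  stopifnot(inherits(dataset, "msi_dataset"))
  names(dataset$channels)
}

resolve_channel <- function(dataset, filter) {
  key <- if (inherits(filter, "scan_filter")) filter_key(filter)
         else as.character(filter)
  ch <- dataset$channels[[key]]
  if (is.null(ch))
    stop("unknown scan filter '", key, "'; available channels: ",
         paste(names(dataset$channels), collapse = ", "))
  ch
}

#' Reconstruct an ion image
#'
#' Builds the spatial intensity map of one target m/z under one scan
#' filter: each valid pixel's value is the summed intensity of peaks within
#' `target_mz +/- tolerance` in that pixel's spectrum. A pixel acquired
#' under the filter but lacking the peak scores 0; a pixel never acquired
#' under the filter is masked invalid and excluded from the pixel count P.
#'
#' @param dataset an `msi_dataset`.
#' @param filter a [scan_filter()] or channel key string.
#' @param target_mz target m/z (Th).
#' @param tolerance half-width of the extraction window (Th); defaults to
#'   0.3 Th for ion-trap channels and 5 ppm for FT channels.
#' @return An object of class `ion_image` with fields `values` (matrix),
#'   `valid_mask`, `P` (number of valid pixels), `target_mz`, `tolerance`
#'   and `filter`.
#' @export
extract_ion_image <- function(dataset, filter, target_mz, tolerance = NULL) {
  ch <- resolve_channel(dataset, filter)
  if (is.null(tolerance))
    tolerance <- if (ch$filter$analyzer == "FT") 5e-6 * target_mz else 0.3
  if (tolerance <= 0) stop("tolerance must be positive")
  vals <- matrix(0, nrow(ch$valid), ncol(ch$valid))
  for (i in which(ch$valid)) {
    p <- ch$spectra[[i]]$peaks
    if (nrow(p)) {
      sel <- abs(p[, 1L] - target_mz) <= tolerance
      if (any(sel)) vals[i] <- sum(p[sel, 2L])
    }
  }
  new_ion_image(vals, ch$valid, target_mz, tolerance, ch$filter)
}

new_ion_image <- function(values, valid_mask, target_mz, tolerance, filter) {
  stopifnot(all(dim(values) == dim(valid_mask)))
  values[!valid_mask] <- 0
  if (any(values < 0)) stop("ion image intensities must be nonnegative")
  structure(list(values = values, valid_mask = valid_mask,
                 P = sum(valid_mask), target_mz = target_mz,
                 tolerance = tolerance, filter = filter),
            class = "ion_image")
}

#' Construct an ion image from a plain matrix
#'
#' Wraps a nonnegative intensity matrix (e.g. a phantom ground-truth map or
#' a matrix read back from TSV) as an `ion_image` so it can enter the SSN
#' pipeline directly.
#'
#' @param values nonnegative intensity matrix (rows = scan lines).
#' @param target_mz nominal m/z label of the image.
#' @param valid_mask logical matrix of acquired pixels; default all valid.
#' @param filter optional [scan_filter()] (defaults to a generic IT MS2
#'   filter label-only placeholder is not created; `NULL` is stored).
#' @return An `ion_image`.
#' @export
ion_image <- function(values, target_mz = NA_real_, valid_mask = NULL,
                      filter = NULL) {
  values <- as.matrix(values)
  if (is.null(valid_mask)) valid_mask <- matrix(TRUE, nrow(values), ncol(values))
  new_ion_image(values, valid_mask, target_mz, NA_real_, filter)
}

#' @export
print.ion_image <- function(x, ...) {
  cat(sprintf("<ion_image> m/z %.4f, %d x %d, P=%d valid, max=%.3g\n",
              x$target_mz, nrow(x$values), ncol(x$values), x$P,
              max(x$values)))
  invisible(x)
}

#' Detect product-ion m/z centers in a channel
#'
#' Builds the mean spectrum over the channel's valid pixels, bins it at
#' `bin_width`, and returns the intensity-weighted centroid of every bin
#' whose total intensity exceeds `min_rel_intensity` of the strongest bin
#' and whose peaks appear in at least `min_pixel_fraction` of the valid
#' pixels. This supplies the product-ion list per isolation window from
#' which ion images are reconstructed.
#'
#' @param dataset an `msi_dataset`.
#' @param filter channel to scan.
#' @param bin_width m/z bin width (Th); 0.5 suits unit-resolution ion-trap
#'   MS2 spectra.
#' @param min_pixel_fraction minimum fraction of valid pixels in which a
#'   bin must contain a peak.
#' @param min_rel_intensity minimum bin intensity relative to the base bin
#'   (0.01 mirrors a 1 %-of-base-peak recovery criterion).
#' @return Numeric vector of m/z centroids, sorted ascending (possibly
#'   empty).
#' @export
detect_product_ions <- function(dataset, filter, bin_width = 0.5,
                                min_pixel_fraction = 0.05,
                                min_rel_intensity = 0.01) {
  if (bin_width <= 0) stop("bin_width must be positive")
  ch <- resolve_channel(dataset, filter)
  P <- sum(ch$valid)
  if (P == 0L) return(numeric(0))
  tot <- new.env(parent = emptyenv())
  for (i in which(ch$valid)) {
    p <- ch$spectra[[i]]$peaks
    if (!nrow(p)) next
    bins <- floor(p[, 1L] / bin_width)
    for (b in unique(bins)) {
      sel <- bins == b
      key <- as.character(b)
      cur <- tot[[key]]
      if (is.null(cur)) cur <- c(int = 0, wmz = 0, npix = 0)
      cur["int"] <- cur["int"] + sum(p[sel, 2L])
      cur["wmz"] <- cur["wmz"] + sum(p[sel, 1L] * p[sel, 2L])
      cur["npix"] <- cur["npix"] + 1
      tot[[key]] <- cur
    }
  }
  keys <- ls(tot)
  if (!length(keys)) return(numeric(0))
  m <- do.call(rbind, lapply(keys, function(k) tot[[k]]))
  base <- max(m[, "int"])
  keep <- m[, "int"] >= min_rel_intensity * base &
    m[, "npix"] >= min_pixel_fraction * P & m[, "int"] > 0
  centers <- m[keep, "wmz"] / m[keep, "int"]
  sort(unname(centers))
}

#' Export an ion image as TSV with a JSON sidecar
#'
#' Writes the intensity matrix as a plain TSV (rows = scan lines) and a
#' `<path>.meta.json` sidecar holding target m/z, tolerance, filter key and
#' the validity mask.
#'
#' @param image an `ion_image`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_ion_image <- function(image, path) {
  stopifnot(inherits(image, "ion_image"))
  write.table(image$values, path, sep = "\t", row.names = FALSE,
              col.names = FALSE)
  meta <- list(target_mz = image$target_mz, tolerance = image$tolerance,
               filter = if (!is.null(image$filter)) filter_key(image$filter)
                        else NA_character_,
               valid_mask = image$valid_mask)
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
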