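#' Spatial phantom for synthetic MS2I data
#'
#' Builds named region masks on a pixel grid, standing in for tissue
#' structures (a white-matter band, a ventricle-like disk, ...). Region
#' types: `full` (whole field), `band` (row or column range), `rect`,
#' `disk` (center + radius, fully inside the field), and `complement` (of a
#' previously defined region). An optional `gradient` (`"linear_x"`,
#' `"linear_y"`) ramps the region weight from 0.2 to 1 across the field,
#' emulating smooth abundance changes; otherwise weights equal the mask.
#'
#' @param shape `c(rows, cols)`, both >= 4.
#' @param regions named list of region specs, e.g.
#'   `list(band = list(type = "band", rows = 3:5))`.
#' @param seed integer seed (kept for reproducibility bookkeeping; current
#'   region types are deterministic).
#' @return Object of class `phantom`: `shape`, logical `masks`, numeric
#'   `weights` (in `[0, 1]`), `seed`.
#' @examples
#' ph <- make_phantom(c(10, 10), list(
#'   band = list(type = "band", rows = 3:5),
#'   disk = list(type = "disk", center = c(7, 7), radius = 2)))
#' sum(ph$masks$band)   # 30 pixels
#' @export
make_phantom <- function(shape, regions, seed = 1L) {
  shape <- as.integer(shape)
  if (length(shape) != 2L || any(shape < 4L))
    stop("phantom shape must be at least 4 x 4")
  if (is.null(names(regions)) || any(names(regions) == ""))
    stop("regions must be a named list")
  set.seed(seed)
  masks <- list(); weights <- list()
  for (nm in names(regions)) {
    spec <- regions[[nm]]
    mask <- switch(spec$type,
      full = matrix(TRUE, shape[1L], shape[2L]),
      band = {
        m <- matrix(FALSE, shape[1L], shape[2L])
        if (!is.null(spec$rows)) {
          if (any(spec$rows < 1L | spec$rows > shape[1L]))
            stop("region '", nm, "' rows fall outside the phantom")
          m[spec$rows, ] <- TRUE
        } else if (!is.null(spec$cols)) {
          if (any(spec$cols < 1L | spec$cols > shape[2L]))
            stop("region '", nm, "' cols fall outside the phantom")
          m[, spec$cols] <- TRUE
        } else stop("band region needs rows or cols")
        m
      },
      rect = {
        if (any(spec$rows < 1L | spec$rows > shape[1L]) ||
            any(spec$cols < 1L | spec$cols > shape[2L]))
          stop("region '", nm, "' falls outside the phantom")
        m <- matrix(FALSE, shape[1L], shape[2L])
        m[spec$rows, spec$cols] <- TRUE
        m
      },
      disk = {
        ctr <- spec$center; r <- spec$radius
        if (length(ctr) != 2L || r < 0 ||
            ctr[1L] - r < 1 || ctr[1L] + r > shape[1L] ||
            ctr[2L] - r < 1 || ctr[2L] + r > shape[2L])
          stop("region '", nm, "' disk falls outside the phantom")
        outer(seq_len(shape[1L]), seq_len(shape[2L]),
              function(i, j) (i - ctr[1L])^2 + (j - ctr[2L])^2 <= r^2)
      },
      complement = {
        if (is.null(masks[[spec$of]]))
          stop("complement region '", nm, "' references unknown region '",
               spec$of, "'")
        !masks[[spec$of]]
      },
      stop("unknown region type '", spec$type, "'"))
    w <- mask * 1
    grad <- spec$gradient
    if (!is.null(grad) && grad != "none") {
      ramp <- switch(grad,
        linear_x = matrix(rep(seq(0.2, 1, length.out = shape[2L]),
                              each = shape[1L]), shape[1L]),
        linear_y = matrix(rep(seq(0.2, 1, length.out = shape[1L]),
                              times = shape[2L]), shape[1L]),
        stop("unknown gradient '", grad, "'"))
      w <- w * ramp
    }
    masks[[nm]] <- mask
    weights[[nm]] <- w
  }
  structure(list(shape = shape, masks = masks, weights = weights,
                 seed = as.integer(seed)),
            class = "phantom")
}

#' Synthetic species specification
#'
#' One co-isolated precursor of the phantom: where it is (a phantom
#' region), how abundant it is, which isolation window fragments it, and
#' its product-ion spectrum. All product ions of a species share the
#' species' spatial distribution, which is the premise SSN exploits.
#'
#' @param name species label.
#' @param precursor_mz precursor m/z (Th).
#' @param window_mz isolation window center the species is fragmented in.
#' @param region name of a phantom region.
#' @param abundance expected peak counts at full region weight.
#' @param fragments data frame (or 2-column matrix) with `mz` and `rel`:
#'   fragment m/z values (< precursor) and relative intensities in (0, 1],
#'   exactly one equal to 1.
#' @return Object of class `species_spec`.
#' @export
species_spec <- function(name, precursor_mz, window_mz, region,
                         abundance = 1000, fragments) {
  fragments <- as.data.frame(fragments)
  names(fragments)[1:2] <- c("mz", "rel")
  if (any(fragments$mz >= precursor_mz))
    stop("all fragment m/z must lie below the precursor m/z")
  if (any(fragments$rel <= 0 | fragments$rel > 1) ||
      sum(fragments$rel == 1) != 1L)
    stop("relative intensities must lie in (0,1] with exactly one base peak")
  structure(list(name = name, precursor_mz = precursor_mz,
                 window_mz = window_mz, region = region,
                 abundance = abundance, fragments = fragments),
            class = "species_spec")
}

#' Noise model for the synthetic writer
#'
#' @param shot Poisson-sample every expected peak intensity (shot noise).
#' @param baseline_peaks mean number of additive baseline peaks per
#'   spectrum (Poisson count; m/z uniform over the scan range, intensity
#'   exponential with mean `baseline_level`).
#' @param baseline_level mean baseline peak intensity (counts).
#' @param dropout_prob per-pixel probability that a low-intensity fragment
#'   peak is unrecorded, emulating low-S/N ions that are not consistently
#'   detected across pixels.
#' @param dropout_max_intensity expected-intensity ceiling below which a
#'   fragment is subject to dropout (`Inf` = all fragments).
#' @param seed optional noise seed; when set it, rather than the
#'   simulation seed, drives the random stream, so one phantom can be
#'   realized under several independent noise draws.
#' @return Object of class `noise_model`.
#' @export
noise_model <- function(shot = FALSE, baseline_peaks = 0, baseline_level = 1,
                        dropout_prob = 0, dropout_max_intensity = Inf,
                        seed = NULL) {
  if (dropout_prob < 0 || dropout_prob > 1)
    stop("dropout_prob must lie in [0, 1]")
  if (baseline_peaks < 0 || baseline_level <= 0)
    stop("baseline_peaks must be >= 0 and baseline_level > 0")
  structure(list(shot = isTRUE(shot), baseline_peaks = baseline_peaks,
                 baseline_level = baseline_level,
                 dropout_prob = dropout_prob,
                 dropout_max_intensity = dropout_max_intensity,
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "noise_model")
}

# complete mzR header row set for one run
build_mzml_header <- function(meta) {
  n <- nrow(meta)
  is2 <- meta$ms_level >= 2L
  filt <- ifelse(is2,
    sprintf("ITMS + c ESI d Full ms2 %.4f@%s30.00",
            meta$isolation_center,
            ifelse(meta$activation == "CID", "cid", "hcd")),
    "FTMS + p ESI Full ms")
  data.frame(
    seqNum = seq_len(n), acquisitionNum = seq_len(n),
    msLevel = as.integer(meta$ms_level), polarity = rep(1L, n),
    peaksCount = meta$peaks_count, totIonCurrent = meta$tic,
    retentionTime = meta$rt,
    basePeakMZ = meta$base_mz, basePeakIntensity = meta$base_int,
    collisionEnergy = ifelse(is2, 30, 0), ionisationEnergy = rep(0, n),
    lowMZ = meta$low_mz, highMZ = meta$high_mz,
    precursorScanNum = rep(0L, n),
    precursorMZ = ifelse(is2, meta$isolation_center, 0),
    precursorCharge = ifelse(is2, 1L, 0L),
    precursorIntensity = rep(0, n),
    mergedScan = rep(0L, n), mergedResultScanNum = rep(0L, n),
    mergedResultStartScanNum = rep(0L, n), mergedResultEndScanNum = rep(0L, n),
    injectionTime = rep(5, n), filterString = filt,
    spectrumId = paste0("scan=", seq_len(n)),
    centroided = rep(TRUE, n), ionMobilityDriftTime = rep(NA_real_, n),
    isolationWindowTargetMZ = ifelse(is2, meta$isolation_center, NA_real_),
    isolationWindowLowerOffset = ifelse(is2, meta$isolation_width / 2,
                                        NA_real_),
    isolationWindowUpperOffset = ifelse(is2, meta$isolation_width / 2,
                                        NA_real_),
    scanWindowLowerLimit = rep(50, n), scanWindowUpperLimit = rep(2000, n),
    stringsAsFactors = FALSE)
}

#' Simulate a ground-truthed MS2I run and write it as mzML
#'
#' Traverses the PIA schedule pixel by pixel and writes one centroided
#' mzML file. FT spectra contain every species' precursor at its exact
#' m/z with region-dependent intensity (abundance x region weight); each
#' MS2 spectrum of an isolation window contains the summed fragment peaks
#' of all species co-isolated in that window and present at that pixel, so
#' overlapping regions produce chimeric spectra. The noise model adds shot
#' noise, baseline peaks and pixel dropout. Byte-reproducible given the
#' seeds.
#'
#' If `acq$inclusion_lists` is unset, inclusion lists are built from the
#' species' isolation windows (round-robin over `acq$n_lists`, padded with
#' empty noise-only windows to equal list lengths).
#'
#' @param phantom a [make_phantom()] phantom; its shape fixes the grid.
#' @param species list of [species_spec()]s.
#' @param acq an [acquisition_config()].
#' @param noise a [noise_model()].
#' @param seed simulation seed; `noise$seed`, when set, overrides it for
#'   the random stream so the same phantom can be re-realized.
#' @param path output mzML path.
#' @param mz_range scan range for baseline peaks.
#' @return Object of class `ms2i_simulation`: `path`, `truth`
#'   (`ms2i_truth`), `grid`, `line_breaks`, `acq`.
#' @export
simulate_dataset <- function(phantom, species, acq, noise = noise_model(),
                             seed = 1L, path = tempfile(fileext = ".mzML"),
                             mz_range = c(100, 1000)) {
  stopifnot(inherits(phantom, "phantom"), inherits(acq, "acquisition_config"),
            inherits(noise, "noise_model"))
  for (sp in species) stopifnot(inherits(sp, "species_spec"))
  centers <- unique(vapply(species, function(s) s$window_mz, numeric(1)))
  if (is.null(acq$inclusion_lists)) {
    N <- acq$n_lists
    W <- max(1L, as.integer(ceiling(length(centers) / N)))
    slots <- W * N
    pad <- if (slots > length(centers))
      max(centers, mz_range[2L]) + 10 * seq_len(slots - length(centers))
    else numeric(0)
    all_centers <- c(sort(centers), pad)
    lists <- lapply(seq_len(N), function(k)
      all_centers[seq(k, slots, by = N)])
    acq <- acquisition_config(
      ft_scan_time_ms = acq$ft_scan_time_ms,
      ft_accumulation_ms = acq$ft_accumulation_ms,
      n_lists = N, windows_per_list = W,
      isolation_width_da = acq$isolation_width_da,
      ft_pixel_x_um = acq$ft_pixel_x_um, ft_pixel_y_um = acq$ft_pixel_y_um,
      inclusion_lists = lists)
  } else {
    avail <- unlist(acq$inclusion_lists)
    miss <- centers[vapply(centers, function(cc)
      all(abs(avail - cc) > 1e-6), logical(1))]
    if (length(miss))
      stop("species windows missing from the inclusion lists: ",
           paste(format(miss), collapse = ", "))
  }
  grid <- pixel_grid(phantom$shape[1L], phantom$shape[2L],
                     n_lists = acq$n_lists,
                     ft_pixel_x_um = acq$ft_pixel_x_um,
                     ft_pixel_y_um = acq$ft_pixel_y_um)
  sched <- build_schedule(acq, grid)
  set.seed(if (!is.null(noise$seed)) noise$seed else as.integer(seed))

  weight_at <- function(sp, r, c) phantom$weights[[sp$region]][r, c]
  baseline <- function(lo, hi) {
    if (noise$baseline_peaks <= 0) return(NULL)
    nb <- rpois(1L, noise$baseline_peaks)
    if (nb == 0L) return(NULL)
    cbind(mz = runif(nb, lo, hi), intensity = rexp(nb, 1 / noise$baseline_level))
  }

  n_scan <- nrow(sched)
  pks <- vector("list", n_scan)
  meta <- data.frame(ms_level = ifelse(sched$scan_type == "FT", 1L, 2L),
                     isolation_center = sched$window_mz,
                     isolation_width = acq$isolation_width_da,
                     activation = "HCD", rt = 0.05 * seq_len(n_scan))
  for (i in seq_len(n_scan)) {
    r <- sched$row[i]; cc <- sched$col[i]
    if (sched$scan_type[i] == "FT") {
      mzv <- numeric(0); iv <- numeric(0)
      for (sp in species) {
        w <- weight_at(sp, r, cc)
        if (w > 0) {
          exp_int <- sp$abundance * w
          obs <- if (noise$shot) rpois(1L, exp_int) else exp_int
          if (obs > 0) { mzv <- c(mzv, sp$precursor_mz); iv <- c(iv, obs) }
        }
      }
      bl <- baseline(mz_range[1L], mz_range[2L])
      if (!is.null(bl)) { mzv <- c(mzv, bl[, 1L]); iv <- c(iv, bl[, 2L]) }
      pks[[i]] <- as_peaklist(mzv, iv)
    } else {
      wc <- sched$window_mz[i]
      mzv <- numeric(0); iv <- numeric(0)
      for (sp in species) {
        if (abs(sp$window_mz - wc) > 1e-6) next
        w <- weight_at(sp, r, cc)
        if (w <= 0) next
        for (fi in seq_len(nrow(sp$fragments))) {
          exp_int <- sp$abundance * sp$fragments$rel[fi] * w
          if (noise$dropout_prob > 0 &&
              exp_int <= noise$dropout_max_intensity &&
              runif(1L) < noise$dropout_prob) next
          obs <- if (noise$shot) rpois(1L, exp_int) else exp_int
          if (obs > 0) { mzv <- c(mzv, sp$fragments$mz[fi]); iv <- c(iv, obs) }
        }
      }
      bl <- baseline(mz_range[1L], min(wc, mz_range[2L]))
      if (!is.null(bl)) { mzv <- c(mzv, bl[, 1L]); iv <- c(iv, bl[, 2L]) }
      pks[[i]] <- as_peaklist(mzv, iv)
    }
  }
  meta$peaks_count <- vapply(pks, nrow, integer(1))
  meta$tic <- vapply(pks, function(p) sum(p[, 2L]), numeric(1))
  meta$base_mz <- vapply(pks, function(p)
    if (nrow(p)) p[which.max(p[, 2L]), 1L] else 0, numeric(1))
  meta$base_int <- vapply(pks, function(p)
    if (nrow(p)) max(p[, 2L]) else 0, numeric(1))
  meta$low_mz <- vapply(pks, function(p)
    if (nrow(p)) min(p[, 1L]) else 0, numeric(1))
  meta$high_mz <- vapply(pks, function(p)
    if (nrow(p)) max(p[, 1L]) else 0, numeric(1))
  mzR::writeMSData(pks, path, header = build_mzml_header(meta))

  per_line <- grid$pixels_per_line * (1L + acq$windows_per_list)
  line_breaks <- 1L + (seq_len(grid$n_lines) - 1L) * per_line

  frag_map <- do.call(rbind, lapply(species, function(sp)
    data.frame(window_mz = sp$window_mz, fragment_mz = sp$fragments$mz,
               species = sp$name, rel = sp$fragments$rel)))
  partition <- lapply(split(species,
                            vapply(species, function(s)
                              sprintf("%.4f", s$window_mz), character(1))),
                      function(sps) {
                        out <- lapply(sps, function(s) s$fragments$mz)
                        names(out) <- vapply(sps, function(s) s$name,
                                             character(1))
                        out
                      })
  truth <- structure(list(
    species = data.frame(
      name = vapply(species, function(s) s$name, character(1)),
      window_mz = vapply(species, function(s) s$window_mz, numeric(1)),
      region = vapply(species, function(s) s$region, character(1)),
      precursor_mz = vapply(species, function(s) s$precursor_mz, numeric(1)),
      abundance = vapply(species, function(s) s$abundance, numeric(1))),
    fragment_map = frag_map,
    expected_partition = partition,
    region_masks = phantom$masks,
    grid = grid, line_breaks = line_breaks, seed = as.integer(seed)),
    class = "ms2i_truth")
  structure(list(path = path, truth = truth, grid = grid,
                 line_breaks = line_breaks, acq = acq),
            class = "ms2i_simulation")
}

#' Serialize ground truth as JSON
#'
#' @param truth an `ms2i_truth`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  stopifnot(inherits(truth, "ms2i_truth"))
  out <- list(species = truth$species, fragment_map = truth$fragment_map,
              expected_partition = truth$expected_partition,
              region_masks = truth$region_masks,
              grid = truth$grid[c("n_lines", "pixels_per_line", "n_lists")],
              line_breaks = truth$line_breaks, seed = truth$seed)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Score cluster recovery against the generator's ground truth
#'
#' For every true species of the isolation window, finds the best-matching
#' cluster and reports its Jaccard index against the species' fragment set
#' (ions matched by m/z within `mz_tol`). The `exact_match` flag is `TRUE`
#' iff the clustering, restricted to the true fragment ions, equals the
#' ground-truth partition: every fragment recovered, fragments of one
#' species together, fragments of different species apart. Noise-derived
#' ions (absent from the truth) never lower a species' Jaccard; they only
#' affect `exact_match` through merges they may cause.
#'
#' @param clusters a `cluster_set` whose ion identifiers parse as m/z.
#' @param truth an `ms2i_truth`.
#' @param window_mz isolation window to score.
#' @param mz_tol ion-matching tolerance (Th).
#' @return List: `per_species` (named Jaccard vector), `exact_match`.
#' @export
evaluate_recovery <- function(clusters, truth, window_mz, mz_tol = 0.3) {
  stopifnot(inherits(clusters, "cluster_set"), inherits(truth, "ms2i_truth"))
  key <- sprintf("%.4f", window_mz)
  truth_sets <- truth$expected_partition[[key]]
  if (is.null(truth_sets))
    stop("no ground truth for window ", key, "; available: ",
         paste(names(truth$expected_partition), collapse = ", "))
  cl_mz <- lapply(clusters$clusters, as.numeric)
  set_jaccard <- function(a, b) {
    if (!length(a) && !length(b)) return(1)
    matched <- 0L
    used <- logical(length(b))
    for (m in a) {
      d <- abs(b - m); d[used] <- Inf
      if (length(d) && min(d) <= mz_tol) {
        used[which.min(d)] <- TRUE
        matched <- matched + 1L
      }
    }
    matched / (length(a) + length(b) - matched)
  }
  # drop noise-derived ions (absent from every truth set) before scoring,
  # but keep other species' fragments so merges are penalized
  union_frags <- unlist(truth_sets, use.names = FALSE)
  truth_only <- lapply(cl_mz, function(cm)
    cm[vapply(cm, function(m) any(abs(union_frags - m) <= mz_tol),
              logical(1))])
  per_species <- vapply(truth_sets, function(fr)
    max(vapply(truth_only, set_jaccard, numeric(1), b = fr)),
    numeric(1))

  # exact-match: map each true fragment to its containing cluster
  all_frags <- unlist(truth_sets, use.names = FALSE)
  frag_species <- rep(names(truth_sets), lengths(truth_sets))
  find_cluster <- function(m) {
    for (i in seq_along(cl_mz))
      if (any(abs(cl_mz[[i]] - m) <= mz_tol)) return(i)
    NA_integer_
  }
  assignment <- vapply(all_frags, find_cluster, integer(1))
  exact <- !anyNA(assignment) &&
    all(tapply(assignment, frag_species,
               function(x) length(unique(x)) == 1L)) &&
    !anyDuplicated(vapply(split(assignment, frag_species), `[`, integer(1), 1L))
  list(per_species = per_species, exact_match = exact)
}
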