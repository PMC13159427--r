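# shared fixtures and independent oracles

# quick ion image from a plain matrix
img <- function(m, mz = NA_real_, mask = NULL) ion_image(as.matrix(m), mz, mask)

# flat image from a vector (1 x n), convenient for hand-computed metrics
vimg <- function(v, mz = NA_real_) ion_image(matrix(v, nrow = 1), mz)

# brute-force connected components by transitive closure of the adjacency
# matrix; independent of igraph
components_oracle <- function(n, edges) {
  reach <- diag(TRUE, n)
  if (nrow(edges)) {
    for (k in seq_len(nrow(edges))) {
      reach[edges[k, 1], edges[k, 2]] <- TRUE
      reach[edges[k, 2], edges[k, 1]] <- TRUE
    }
  }
  repeat {
    nxt <- (reach %*% reach) > 0
    if (all(nxt == reach)) break
    reach <- nxt
  }
  membership <- integer(n)
  comp <- 0L
  for (i in seq_len(n)) {
    if (membership[i] == 0L) {
      comp <- comp + 1L
      membership[reach[i, ]] <- comp
    }
  }
  membership
}

# canonical form of a partition for comparison: sorted list of sorted sets
canonical_partition <- function(sets) {
  sets <- lapply(sets, function(s) sort(as.character(s)))
  sets[order(vapply(sets, function(s) s[1], character(1)))]
}

partition_from_membership <- function(ids, membership) {
  canonical_partition(unname(split(ids, membership)))
}

# the demo isolation-window cast: three co-isolated PC isobars near
# m/z 808.6 with distinct spatial distributions
demo_phantom <- function(shape = c(12, 12)) {
  r1 <- max(2L, round(shape[1] * 0.25))
  r2 <- max(r1, round(shape[1] * 0.4))
  ctr <- pmin(ceiling(shape * 0.7), shape - 1L)
  rad <- max(1L, min(floor(min(shape) / 6), ctr - 1L, shape - ctr))
  make_phantom(shape, list(
    band = list(type = "band", rows = r1:r2),
    disk = list(type = "disk", center = ctr, radius = rad),
    full = list(type = "full")))
}

demo_species <- function() {
  list(
    species_spec("PC(18:0_18:2)+Na", 808.5832, 808.6, "band", 1000,
                 data.frame(mz = c(465.3, 469.3, 749.5), rel = c(1, 0.6, 0.3))),
    species_spec("PC(38:5)+H", 808.5856, 808.6, "disk", 800,
                 data.frame(mz = c(184.1, 625.5, 549.5), rel = c(1, 0.5, 0.2))),
    species_spec("PC(O-36:3)+K", 808.5622, 808.6, "full", 500,
                 data.frame(mz = c(146.9, 565.5), rel = c(1, 0.5))))
}

demo_acq <- function(n_lists = 1L, windows_per_list = 1L, ...) {
  acquisition_config(n_lists = n_lists, windows_per_list = windows_per_list,
                     ...)
}

# simulate the demo window end to end and return clustered images + truth
simulate_demo_window <- function(seed = 1, noise = noise_model(),
                                 shape = c(12, 12)) {
  sim <- simulate_dataset(demo_phantom(shape), demo_species(), demo_acq(),
                          noise = noise, seed = seed)
  on.exit(unlink(c(sim$path, paste0(sim$path, ".ssnmsi"))), add = TRUE)
  ds <- assign_pixels(read_mzml(sim$path), sim$grid, sim$line_breaks)
  key <- grep("MS2", channel_keys(ds), value = TRUE)[1]
  ions <- detect_product_ions(ds, key)
  images <- lapply(ions, function(m) extract_ion_image(ds, key, m))
  names(images) <- sprintf("%.4f", ions)
  list(images = images, truth = sim$truth, dataset = ds, key = key)
}

# minimal empty mzML document (0 spectra)
empty_mzml_text <- function() {
'<?xml version="1.0" encoding="utf-8"?>
<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1.0">
  <cvList count="1">
    <cv id="MS" fullName="PSI-MS" URI="https://raw.githubusercontent.com/HUPO-PSI/psi-ms-CV/master/psi-ms.obo"/>
  </cvList>
  <fileDescription><fileContent>
    <cvParam cvRef="MS" accession="MS:1000579" name="MS1 spectrum" value=""/>
  </fileContent></fileDescription>
  <softwareList count="1"><software id="sw" version="0.1"/></softwareList>
  <instrumentConfigurationList count="1"><instrumentConfiguration id="IC1"/></instrumentConfigurationList>
  <dataProcessingList count="1"><dataProcessing id="dp"><processingMethod order="1" softwareRef="sw"/></dataProcessing></dataProcessingList>
  <run id="run1" defaultInstrumentConfigurationRef="IC1">
    <spectrumList count="0" defaultDataProcessingRef="dp">
    </spectrumList>
  </run>
</mzML>'
}

# fabricate spectrum records directly (acquisition-order stream) for
# assign_pixels tests without touching disk
fake_record <- function(index, ms_level, center = NULL, width = 0.7,
                        peaks = NULL, rt = index) {
  filt <- if (ms_level == 1L) scan_filter("FT", 1L)
  else scan_filter("IT", 2L, isolation_center = center,
                   isolation_width = width, activation = "HCD")
  if (is.null(peaks))
    peaks <- matrix(numeric(0), ncol = 2,
                    dimnames = list(NULL, c("mz", "intensity")))
  ssnmsi:::new_spectrum_record(index, filt, peaks, rt)
}

# one scan line of FT pixels with per-pixel MS2 windows cycling N lists
fake_line <- function(n_pixels, lists, start_index = 0L, row_peaks = NULL) {
  recs <- list()
  idx <- start_index
  N <- length(lists)
  for (px in seq_len(n_pixels)) {
    recs[[length(recs) + 1L]] <- fake_record(idx, 1L)
    idx <- idx + 1L
    for (w in lists[[(px - 1L) %% N + 1L]]) {
      pk <- if (is.null(row_peaks)) NULL else row_peaks(px, w)
      recs[[length(recs) + 1L]] <- fake_record(idx, 2L, center = w,
                                               peaks = pk)
      idx <- idx + 1L
    }
  }
  recs
}
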