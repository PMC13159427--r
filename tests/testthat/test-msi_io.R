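test_that("mzML round trip preserves record count, levels and peaks", {
  ph <- make_phantom(c(4, 4), list(full = list(type = "full")))
  sp <- list(species_spec("X", 500.5, 500.5, "full", 100,
                          data.frame(mz = c(200.1, 300.2), rel = c(1, 0.5))),
             species_spec("Y", 520.5, 520.5, "full", 50,
                          data.frame(mz = 250.3, rel = 1)))
  acq <- demo_acq(n_lists = 1, windows_per_list = 2)
  sim <- simulate_dataset(ph, sp, acq, seed = 3)
  withr::defer(unlink(sim$path))
  recs <- read_mzml(sim$path)
  # 16 pixels x (1 FT + 2 MS2)
  expect_length(recs, 48)
  lvls <- vapply(recs, function(r) r$filter$ms_level, integer(1))
  expect_equal(lvls, rep(c(1L, 2L, 2L), 16))
  expect_equal(vapply(recs, function(r) r$index, integer(1)), 0:47)
  rts <- vapply(recs, function(r) r$retention_time, numeric(1))
  expect_false(is.unsorted(rts))
  # peak m/z and intensities survive the binary encoding exactly
  ms2 <- recs[[2]]
  expect_equal(ms2$filter$isolation_center, 500.5, tolerance = 1e-9)
  expect_equal(ms2$filter$isolation_width, 0.7, tolerance = 1e-9)
  expect_identical(unname(ms2$peaks[, "mz"]), c(200.1, 300.2))
  expect_identical(unname(ms2$peaks[, "intensity"]), c(100, 50))
})

test_that("an empty run reads as an empty record list", {
  path <- withr::local_tempfile(fileext = ".mzML")
  writeLines(empty_mzml_text(), path)
  expect_length(read_mzml(path), 0)
})

test_that("an MS2 spectrum without isolation metadata is a hard error", {
  path <- withr::local_tempfile(fileext = ".mzML")
  meta <- data.frame(ms_level = 2L, isolation_center = 500, isolation_width = 0.7,
                     activation = "HCD", rt = 1, peaks_count = 1L, tic = 1,
                     base_mz = 200, base_int = 1, low_mz = 200, high_mz = 200)
  hdr <- ssnmsi:::build_mzml_header(meta)
  hdr$isolationWindowTargetMZ <- NA_real_
  hdr$precursorMZ <- 0
  hdr$isolationWindowLowerOffset <- NA_real_
  hdr$isolationWindowUpperOffset <- NA_real_
  mzR::writeMSData(list(cbind(mz = 200, intensity = 1)), path, header = hdr)
  expect_error(read_mzml(path), "index 0.*isolation|isolation.*index 0")
})

test_that("assign_pixels places channels on the grid without list cycling", {
  # N=1, n=2: every MS2 filter keeps the full 2x2 grid
  lists <- list(c(400.5, 600.5))
  recs <- c(fake_line(2, lists), fake_line(2, lists, start_index = 6L))
  grid <- pixel_grid(2, 2, n_lists = 1)
  ds <- assign_pixels(recs, grid, line_breaks = c(1, 7))
  expect_length(recs, 12)
  expect_setequal(channel_keys(ds),
                  c("FT MS1", "IT MS2 400.5000/0.70 HCD L0",
                    "IT MS2 600.5000/0.70 HCD L0"))
  for (k in channel_keys(ds)) {
    expect_equal(dim(ds$channels[[k]]$valid), c(2, 2))
    expect_true(all(ds$channels[[k]]$valid))
  }
})

test_that("assign_pixels downsamples MS2 channels N-fold along x", {
  # N=4 lists of 27 windows, one line of 108 FT pixels
  lists <- lapply(0:3, function(k) 1000 + 27 * k + seq_len(27))
  recs <- fake_line(108, lists)
  grid <- pixel_grid(1, 108, n_lists = 4)
  ds <- assign_pixels(recs, grid, line_breaks = 1)
  keys <- grep("MS2", channel_keys(ds), value = TRUE)
  expect_length(keys, 108)
  for (k in keys) {
    expect_equal(ncol(ds$channels[[k]]$valid), 27)
    expect_true(all(ds$channels[[k]]$valid))
  }
  # valid columns of list k map back to FT columns == k (mod N)
  for (k in keys) {
    li <- ds$channels[[k]]$filter$list_index
    ft_cols <- which(ds$channels[[k]]$valid[1, ]) * 4 - 4 + li + 1
    expect_true(all((ft_cols - 1) %% 4 == li))
  }
})

test_that("an odd line under N=2 leaves the trailing pixel masked", {
  lists <- list(400.5, 600.5)   # list 0 and list 1, one window each
  recs <- fake_line(5, lists)
  grid <- pixel_grid(1, 5, n_lists = 2)
  ds <- assign_pixels(recs, grid, line_breaks = 1)
  v0 <- ds$channels[["IT MS2 400.5000/0.70 HCD L0"]]$valid
  v1 <- ds$channels[["IT MS2 600.5000/0.70 HCD L1"]]$valid
  expect_equal(sum(v0), 3)      # FT columns 1, 3, 5
  expect_equal(sum(v1), 2)      # FT columns 2, 4
  expect_false(v1[1, 3])        # trailing cycle never reaches list 1
})

test_that("a record stream inconsistent with the grid is rejected", {
  recs <- fake_line(3, list(400.5))
  grid <- pixel_grid(1, 4, n_lists = 1)
  expect_error(assign_pixels(recs, grid, line_breaks = 1),
               "expected 4 FT pixels, found 3")
})

test_that("extract_ion_image sums windowed peaks per pixel", {
  lists <- list(500.5)
  pkfun <- function(px, w) {
    if (px == 1) cbind(mz = c(500.3, 500.8), intensity = c(100, 50))
    else matrix(numeric(0), ncol = 2)
  }
  recs <- c(fake_line(2, lists, row_peaks = pkfun),
            fake_line(2, lists, start_index = 4L))
  ds <- assign_pixels(recs, pixel_grid(2, 2), line_breaks = c(1, 5))
  im <- extract_ion_image(ds, "IT MS2 500.5000/0.70 HCD L0", 500.3,
                          tolerance = 0.3)
  expect_equal(im$values, matrix(c(100, 0, 0, 0), 2, 2))
  expect_equal(im$P, 4)
  # widen to cover both peaks
  im2 <- extract_ion_image(ds, "IT MS2 500.5000/0.70 HCD L0", 500.5,
                           tolerance = 0.4)
  expect_equal(im2$values[1, 1], 150)
  # all-empty pixels give an all-zero image with the correct mask
  im0 <- extract_ion_image(ds, "IT MS2 500.5000/0.70 HCD L0", 999,
                           tolerance = 0.3)
  expect_true(all(im0$values == 0))
  expect_true(all(im0$valid_mask))
  expect_error(extract_ion_image(ds, "IT MS2 123.0000/0.70 HCD L0", 500, 0.3),
               "unknown scan filter")
})

test_that("extract_ion_image is additive over disjoint sub-windows", {
  sim <- simulate_demo_window(seed = 11)
  ds <- sim$dataset
  whole <- extract_ion_image(ds, sim$key, 500, tolerance = 400)
  parts <- list(extract_ion_image(ds, sim$key, 250, tolerance = 150),
                extract_ion_image(ds, sim$key, 650.5, tolerance = 250.5))
  # [100,400] and (400,901] partition [100,900]
  expect_equal(whole$values, parts[[1]]$values + parts[[2]]$values,
               tolerance = 1e-12)
})

test_that("phantom species images are nonzero exactly on their region", {
  sim <- simulate_demo_window(seed = 5)
  band_img <- sim$images[["465.3000"]]
  expect_equal(band_img$values > 0, sim$truth$region_masks$band)
  disk_img <- sim$images[["184.1000"]]
  expect_equal(disk_img$values > 0, sim$truth$region_masks$disk)
})

test_that("detect_product_ions finds exactly the emitted fragment centers", {
  ph <- make_phantom(c(4, 4), list(full = list(type = "full")))
  sp <- list(species_spec("S", 500.5, 500.5, "full", 100,
                          data.frame(mz = c(465, 467, 469),
                                     rel = c(1, 0.9, 0.8))))
  sim <- simulate_dataset(ph, sp, demo_acq(), seed = 2)
  withr::defer(unlink(sim$path))
  ds <- assign_pixels(read_mzml(sim$path), sim$grid, sim$line_breaks)
  key <- grep("MS2", channel_keys(ds), value = TRUE)
  centers <- detect_product_ions(ds, key)
  expect_length(centers, 3)
  expect_equal(centers, c(465, 467, 469), tolerance = 0.25)
})

test_that("detect_product_ions returns empty for sparse random noise", {
  ph <- make_phantom(c(6, 6), list(full = list(type = "full")))
  sp <- list(species_spec("S", 500.5, 500.5, "full", 1e-9,
                          data.frame(mz = 200, rel = 1)))
  sim <- simulate_dataset(ph, sp, demo_acq(),
                          noise = noise_model(baseline_peaks = 1,
                                              baseline_level = 5, seed = 42),
                          seed = 42)
  withr::defer(unlink(sim$path))
  ds <- assign_pixels(read_mzml(sim$path), sim$grid, sim$line_breaks)
  key <- grep("MS2", channel_keys(ds), value = TRUE)
  # scattered baseline peaks never recur in >= 50% of pixels
  expect_length(detect_product_ions(ds, key, min_pixel_fraction = 0.5), 0)
})

test_that("duplicate peaks inside one bin collapse to one centroid", {
  lists <- list(500.5)
  pkfun <- function(px, w) cbind(mz = c(465.1, 465.3), intensity = c(10, 10))
  recs <- fake_line(4, lists, row_peaks = pkfun)
  ds <- assign_pixels(recs, pixel_grid(1, 4), line_breaks = 1)
  centers <- detect_product_ions(ds, "IT MS2 500.5000/0.70 HCD L0")
  expect_length(centers, 1)
  expect_equal(centers, 465.2, tolerance = 1e-9)
})

test_that("ion images export to TSV with a JSON sidecar", {
  im <- img(matrix(1:6, 2, 3), mz = 465.3)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_ion_image(im, path)
  back <- as.matrix(read.delim(path, header = FALSE))
  expect_equal(unname(back), unname(im$values))
  meta <- jsonlite::read_json(paste0(path, ".meta.json"))
  expect_equal(meta$target_mz, 465.3)
})
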