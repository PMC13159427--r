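test_that("cosine similarity matches hand-computed values", {
  x <- vimg(c(1, 0, 2, 0))
  expect_equal(as.numeric(image_cosine(x, x)), 1)
  x3 <- vimg(c(3, 0, 6, 0))
  expect_equal(as.numeric(image_cosine(x, x3)), 1, tolerance = 1e-12)
  y <- vimg(c(0, 3, 0, 1))
  expect_equal(as.numeric(image_cosine(x, y)), 0)
  expect_equal(as.numeric(image_cosine(vimg(c(1, 2)), vimg(c(2, 1)))), 0.8)
  # degenerate all-zero image scores 0 and is flagged
  z <- vimg(c(0, 0, 0, 0))
  s <- image_cosine(x, z)
  expect_equal(as.numeric(s), 0)
  expect_true(attr(s, "degenerate"))
  expect_error(image_cosine(x, vimg(c(1, 2))), "incompatible")
})

test_that("cosine is scale-invariant, SSE/MSE are intensity-sensitive", {
  set.seed(101)
  for (i in 1:20) {
    v <- rexp(24)
    c_ <- runif(1, 0.1, 50)
    a <- vimg(v); b <- vimg(c_ * v)
    expect_equal(as.numeric(image_cosine(a, b)), 1, tolerance = 1e-12)
    expect_gt(image_sse(a, vimg(3 * v)), 0)
  }
})

test_that("SSE and MSE match hand arithmetic", {
  x <- vimg(c(1, 2)); y <- vimg(c(3, 0))
  expect_equal(image_sse(x, x), 0)
  expect_equal(image_sse(x, y), 8)
  expect_equal(image_mse(x, y), 4)
  # unit_max normalization removes pure scale differences
  expect_equal(image_sse(x, vimg(c(2, 4)), normalization = "unit_max"), 0)
})

test_that("similarity_matrix is symmetric and equals a naive double loop", {
  expect_error(similarity_matrix(list()), "at least one image")
  one <- similarity_matrix(list(a = vimg(c(1, 2))))
  expect_equal(one$S, matrix(1, 1, 1, dimnames = list("a", "a")))
  one_sse <- similarity_matrix(list(a = vimg(c(1, 2))), metric_spec("sse"))
  expect_equal(unname(one_sse$S), matrix(0, 1, 1))

  set.seed(7)
  imgs <- lapply(1:5, function(i) img(matrix(rexp(20), 4, 5)))
  names(imgs) <- paste0("ion", 1:5)
  for (mname in c("cosine", "sse", "mse")) {
    sm <- similarity_matrix(imgs, metric_spec(mname, "none"))
    expect_identical(sm$S, t(sm$S))
    naive <- matrix(0, 5, 5)
    for (i in 1:5) for (j in 1:5) {
      xi <- imgs[[i]]$values; xj <- imgs[[j]]$values
      naive[i, j] <- switch(mname,
        cosine = sum(xi * xj) / sqrt(sum(xi^2) * sum(xj^2)),
        sse = sum((xi - xj)^2),
        mse = sum((xi - xj)^2) / 20)
    }
    expect_equal(unname(sm$S), naive, tolerance = 1e-12)
  }
})

test_that("threshold rules create the expected edges", {
  set.seed(3)
  imgs <- lapply(1:4, function(i) img(matrix(rexp(16), 4, 4)))
  names(imgs) <- letters[1:4]
  sm <- similarity_matrix(imgs)
  g_none <- build_ssn_graph(sm, cluster_params(1.01))
  expect_equal(igraph::ecount(g_none), 0)
  cs <- ssn_components(g_none)
  expect_length(cs$clusters, 4)
  expect_true(all(cs$singlet))
  g_all <- build_ssn_graph(sm, cluster_params(0))
  expect_equal(igraph::ecount(g_all), 6)   # complete graph on 4 nodes
  expect_error(build_ssn_graph(sm, cluster_params(0.5, metric_spec("sse"))),
               "does not match")
  expect_error(cluster_params(-0.1), "cannot be negative")
})

test_that("connected components agree with transitive-closure oracle", {
  set.seed(42)
  # exhaustive sizes up to 8 nodes, random edge sets
  for (rep in 1:200) {
    n <- sample(2:8, 1)
    npairs <- n * (n - 1) / 2
    pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    sel <- runif(npairs) < 0.25
    edges <- pairs[sel, , drop = FALSE]
    S <- diag(1, n)
    if (nrow(edges))
      for (k in seq_len(nrow(edges)))
        S[edges[k, 1], edges[k, 2]] <- S[edges[k, 2], edges[k, 1]] <- 1
    ids <- paste0("n", seq_len(n))
    dimnames(S) <- list(ids, ids)
    sm <- structure(list(ions = ids, S = S, metric = metric_spec("cosine"),
                         degenerate = rep(FALSE, n)),
                    class = "similarity_matrix")
    cs <- ssn_components(build_ssn_graph(sm, cluster_params(1)))
    expect_identical(canonical_partition(cs$clusters),
                     partition_from_membership(ids, components_oracle(n, edges)))
  }
  # 100 random 15-node graphs
  for (rep in 1:100) {
    n <- 15
    pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    sel <- runif(nrow(pairs)) < 0.08
    edges <- pairs[sel, , drop = FALSE]
    S <- diag(1, n)
    if (nrow(edges))
      for (k in seq_len(nrow(edges)))
        S[edges[k, 1], edges[k, 2]] <- S[edges[k, 2], edges[k, 1]] <- 1
    ids <- paste0("n", seq_len(n))
    dimnames(S) <- list(ids, ids)
    sm <- structure(list(ions = ids, S = S, metric = metric_spec("cosine"),
                         degenerate = rep(FALSE, n)),
                    class = "similarity_matrix")
    cs <- ssn_components(build_ssn_graph(sm, cluster_params(1)))
    expect_identical(canonical_partition(cs$clusters),
                     partition_from_membership(ids, components_oracle(n, edges)))
  }
})

test_that("textbook component cases partition correctly", {
  ids <- c("a", "b", "c", "d", "e")
  S <- diag(1, 5); dimnames(S) <- list(ids, ids)
  S["a", "b"] <- S["b", "a"] <- 1
  S["b", "c"] <- S["c", "b"] <- 1
  S["d", "e"] <- S["e", "d"] <- 1
  sm <- structure(list(ions = ids, S = S, metric = metric_spec("cosine"),
                       degenerate = rep(FALSE, 5)),
                  class = "similarity_matrix")
  cs <- ssn_components(build_ssn_graph(sm, cluster_params(1)))
  expect_identical(canonical_partition(cs$clusters),
                   canonical_partition(list(c("a", "b", "c"), c("d", "e"))))
  expect_equal(sum(cs$singlet), 0)
  # cluster sets are always partitions
  expect_setequal(unlist(cs$clusters), ids)
})

test_that("raising a similarity threshold only refines the partition", {
  set.seed(99)
  for (rep in 1:50) {
    n <- 8
    M <- matrix(runif(n * n), n, n)
    S <- (M + t(M)) / 2; diag(S) <- 1
    ids <- paste0("n", seq_len(n)); dimnames(S) <- list(ids, ids)
    sm <- structure(list(ions = ids, S = S, metric = metric_spec("cosine"),
                         degenerate = rep(FALSE, n)),
                    class = "similarity_matrix")
    taus <- sort(runif(3))
    parts <- lapply(taus, function(tau)
      ssn_components(build_ssn_graph(sm, cluster_params(tau)))$clusters)
    for (i in 1:2) {
      coarse <- parts[[i]]; fine <- parts[[i + 1]]
      for (cl in fine) {
        containing <- vapply(coarse, function(co) all(cl %in% co), logical(1))
        expect_equal(sum(containing), 1)
      }
    }
  }
})

test_that("low-S/N dropout-heavy ions remain singlets at high threshold", {
  noisy <- noise_model(dropout_prob = 0.6, dropout_max_intensity = 20,
                       seed = 17)
  ph <- demo_phantom()
  sp <- c(demo_species(),
          list(species_spec("lowSN", 808.59, 808.6, "full", 20,
                            data.frame(mz = 350.2, rel = 1))))
  sim <- simulate_dataset(ph, sp, demo_acq(), noise = noisy, seed = 17)
  withr::defer(unlink(sim$path))
  ds <- assign_pixels(read_mzml(sim$path), sim$grid, sim$line_breaks)
  key <- grep("MS2", channel_keys(ds), value = TRUE)
  ions <- detect_product_ions(ds, key)
  expect_true(any(abs(ions - 350.2) < 0.3))
  images <- lapply(ions, function(m) extract_ion_image(ds, key, m))
  names(images) <- sprintf("%.4f", ions)
  cs <- ssn_cluster(images, cluster_params(0.95))
  holder <- which(vapply(cs$clusters,
                         function(cl) any(abs(as.numeric(cl) - 350.2) < 0.3),
                         logical(1)))
  expect_length(cs$clusters[[holder]], 1)
  expect_true(cs$singlet[holder])
})

test_that("patch pooling reduces to plain SSN at p = 1 and pools means", {
  set.seed(5)
  imgs <- lapply(1:4, function(i) img(matrix(rexp(48), 6, 8)))
  names(imgs) <- letters[1:4]
  p1 <- coherent_ssn(imgs, cluster_params(0.7, patch = patch_config(1)))
  plain <- ssn_cluster(imgs, cluster_params(0.7))
  expect_identical(canonical_partition(p1$clusters),
                   canonical_partition(plain$clusters))
  pooled <- pool_image(imgs[[1]], patch_config(2))
  expect_equal(dim(pooled$values), c(3, 4))
  expect_equal(pooled$values[1, 1], mean(imgs[[1]]$values[1:2, 1:2]))
  expect_error(pool_image(imgs[[1]], patch_config(10)), "exceeds both")
  # constant images cluster together at any threshold <= 1 regardless of p
  const <- lapply(1:3, function(i) img(matrix(5, 8, 8)))
  names(const) <- letters[1:3]
  cc <- coherent_ssn(const, cluster_params(1, patch = patch_config(4)))
  expect_length(cc$clusters, 1)
})

test_that("coherent SSN recovers clusters that salt noise splits", {
  # two ions share a band distribution; 5% of pixels of one are blasted
  set.seed(23)
  base <- matrix(0, 16, 16); base[6:10, ] <- 100
  salted <- base
  hits <- sample(length(salted), ceiling(0.05 * length(salted)))
  salted[hits] <- salted[hits] + 4000
  imgs <- list(clean = img(base), noisy = img(salted))
  plain <- ssn_cluster(imgs, cluster_params(0.9))
  expect_length(plain$clusters, 2)   # salt breaks the correlation
  coh <- coherent_ssn(imgs, cluster_params(0.9, patch = patch_config(4,
                                                                     "median")))
  expect_length(coh$clusters, 1)     # pooling restores it
})

test_that("cluster spectra reproduce generator fragment ratios", {
  sim <- simulate_demo_window(seed = 2)
  cs <- ssn_cluster(sim$images, cluster_params(0.9))
  band_cl <- cs$clusters[[which(vapply(cs$clusters, function(cl)
    any(abs(as.numeric(cl) - 465.3) < 0.3), logical(1)))]]
  spec <- cluster_spectrum(band_cl, sim$images)
  expect_equal(spec$mz, c(465.3, 469.3, 749.5), tolerance = 0.3)
  expect_equal(spec$intensity, c(100, 60, 30), tolerance = 1e-6)
  # single-ion cluster
  single <- cluster_spectrum(band_cl[1], sim$images)
  expect_equal(single$intensity, 100)
  # empty and all-zero cases are degenerate
  e <- cluster_spectrum(character(0), sim$images)
  expect_equal(nrow(e), 0)
  expect_true(attr(e, "degenerate"))
})

test_that("reference comparison applies the 1% base-peak criterion", {
  ref <- data.frame(mz = c(184.1, 603.5), intensity = c(100, 40))
  dec <- data.frame(mz = 184.1, intensity = 100)
  expect_equal(compare_to_reference(dec, ref, mz_tol = 0.3)$recovery, 0.5)
  expect_equal(compare_to_reference(ref, ref)$recovery, 1)
  # a 0.5%-of-base reference peak is excluded from the denominator
  ref2 <- data.frame(mz = c(184.1, 300.2), intensity = c(100, 0.5))
  cmp <- compare_to_reference(dec, ref2, mz_tol = 0.3, min_rel = 0.01)
  expect_equal(cmp$recovery, 1)
  expect_length(cmp$unmatched_reference, 0)
})

test_that("replicate Jaccard handles identity, disjoint and the 17/19 case", {
  a <- 100 + 1:5
  expect_equal(cluster_jaccard(list(a, a))$jaccard, 1)
  expect_equal(cluster_jaccard(list(a, a + 50))$jaccard, 0)
  expect_error(cluster_jaccard(list(a)), "at least two")
  ions <- 400 + seq_len(19)
  reps <- list(ions[1:18], ions[c(1:17, 19)], ions[1:17])
  cmp <- cluster_jaccard(reps)
  expect_equal(length(cmp$union_ions), 19)
  expect_equal(length(cmp$shared_ions), 17)
  expect_equal(round(cmp$jaccard, 3), 0.895)
  # tolerance matching aligns slightly shifted m/z across replicates
  cmp2 <- cluster_jaccard(list(ions[1:17], ions[1:17] + 0.1), mz_tol = 0.3)
  expect_equal(cmp2$jaccard, 1)
})

test_that("cluster tables round-trip through TSV", {
  cs <- structure(list(clusters = list(c("465.3", "469.3"), "184.1"),
                       singlet = c(FALSE, TRUE),
                       nodes = c("465.3", "469.3", "184.1")),
                  class = "cluster_set")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_cluster_table(cs, path)
  back <- read.delim(path)
  expect_equal(nrow(back), 3)
  expect_equal(sort(unique(back$cluster)), c(1, 2))
})
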