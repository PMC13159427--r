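#' Spatial similarity metric specification
#'
#' The three metrics compared on product-ion images. Cosine similarity is
#' independent of absolute intensity, which makes it the robust default
#' across datasets acquired under different conditions; SSE and MSE account
#' for absolute intensity and are therefore sensitive to it. Orientation is
#' fixed by the metric: cosine is a similarity (edge when the score is at
#' least the threshold), SSE/MSE are dissimilarities (edge when the score
#' is at most the threshold).
#'
#' @param name `"cosine"`, `"sse"` or `"mse"`.
#' @param per_image_normalization `"none"`, `"unit_max"` (divide by the
#'   image maximum) or `"unit_norm"` (divide by the Euclidean norm),
#'   applied to each image before scoring. Defaults: `"none"` for cosine
#'   (which is scale-invariant anyway), `"unit_max"` for SSE/MSE so their
#'   thresholds are comparable across ions of different abundance.
#' @return An object of class `metric_spec` with the derived `orientation`.
#' @export
metric_spec <- function(name = c("cosine", "sse", "mse"),
                        per_image_normalization = NULL) {
  name <- match.arg(name)
  orientation <- if (name == "cosine") "similarity" else "dissimilarity"
  if (is.null(per_image_normalization))
    per_image_normalization <- if (name == "cosine") "none" else "unit_max"
  per_image_normalization <- match.arg(per_image_normalization,
                                       c("none", "unit_max", "unit_norm"))
  structure(list(name = name, orientation = orientation,
                 per_image_normalization = per_image_normalization),
            class = "metric_spec")
}

#' @export
print.metric_spec <- function(x, ...) {
  cat(sprintf("<metric_spec> %s (%s; per-image normalization: %s)\n",
              x$name, x$orientation, x$per_image_normalization))
  invisible(x)
}

check_compatible <- function(a, b) {
  stopifnot(inherits(a, "ion_image"), inherits(b, "ion_image"))
  if (!all(dim(a$values) == dim(b$values)))
    stop("ion images have incompatible shapes")
  if (!all(a$valid_mask == b$valid_mask))
    stop("ion images have incompatible validity masks")
  invisible(TRUE)
}

normalize_values <- function(x, how) {
  switch(how,
         none = x,
         unit_max = if (max(x) > 0) x / max(x) else x,
         unit_norm = if (sum(x^2) > 0) x / sqrt(sum(x^2)) else x)
}

#' Cosine similarity between two ion images
#'
#' `sum(x*y) / (||x|| * ||y||)` over the jointly valid pixels. Returns 0
#' (flagged degenerate via attribute) when either image is all-zero.
#' Scale-invariant: `cosine(x, c*x) = 1` for any `c > 0`.
#'
#' @param a,b co-registered [ion_image()]s (same shape and mask).
#' @return Score in `[0, 1]` for nonnegative images; attribute `degenerate`
#'   is `TRUE` when either vector was all-zero.
#' @export
image_cosine <- function(a, b) {
  check_compatible(a, b)
  x <- a$values[a$valid_mask]; y <- b$values[b$valid_mask]
  nx <- sqrt(sum(x^2)); ny <- sqrt(sum(y^2))
  if (nx == 0 || ny == 0)
    return(structure(0, degenerate = TRUE))
  sum(x * y) / (nx * ny)
}

#' Sum and mean of squared error between ion images
#'
#' `image_sse` is `sum((x - y)^2)` over jointly valid pixels after the
#' metric's per-image normalization; `image_mse` divides by the number of
#' valid pixels P. Unlike cosine similarity these depend on absolute
#' intensity (under `normalization = "none"`).
#'
#' @param a,b co-registered [ion_image()]s.
#' @param normalization per-image normalization applied before the
#'   difference; see [metric_spec()].
#' @return Nonnegative error value.
#' @export
image_sse <- function(a, b, normalization = "none") {
  check_compatible(a, b)
  x <- normalize_values(a$values[a$valid_mask], normalization)
  y <- normalize_values(b$values[b$valid_mask], normalization)
  sum((x - y)^2)
}

#' @rdname image_sse
#' @export
image_mse <- function(a, b, normalization = "none") {
  image_sse(a, b, normalization) / a$P
}

#' Pairwise similarity matrix of product-ion images
#'
#' Scores every unordered pair of images once under the chosen metric. The
#' result is symmetric with the metric's fixed diagonal (1 for cosine, 0
#' for SSE/MSE). Degenerate (all-zero) images are recorded, not dropped:
#' they score 0 similarity (or keep their raw SSE/MSE) against everything
#' and end up as singlets downstream.
#'
#' @param images list of co-registered [ion_image()]s; names are used as
#'   ion identifiers (default: the formatted target m/z).
#' @param metric a [metric_spec()].
#' @return Object of class `similarity_matrix`: `ions` (identifiers), `S`
#'   (square symmetric matrix), `metric`, `degenerate` (logical per ion).
#' @export
similarity_matrix <- function(images, metric = metric_spec("cosine")) {
  if (length(images) == 0L) stop("similarity_matrix needs at least one image")
  stopifnot(inherits(metric, "metric_spec"))
  ids <- names(images)
  if (is.null(ids))
    ids <- vapply(images, function(im) sprintf("%.4f", im$target_mz),
                  character(1))
  if (anyDuplicated(ids)) stop("ion identifiers must be unique")
  k <- length(images)
  for (i in seq_len(k)[-1]) check_compatible(images[[1L]], images[[i]])
  degenerate <- vapply(images, function(im) max(im$values) == 0, logical(1))
  S <- matrix(if (metric$name == "cosine") 1 else 0, k, k,
              dimnames = list(ids, ids))
  if (k > 1L) {
    for (i in seq_len(k - 1L)) {
      for (j in seq(i + 1L, k)) {
        s <- switch(metric$name,
          cosine = as.numeric(image_cosine(images[[i]], images[[j]])),
          sse = image_sse(images[[i]], images[[j]],
                          metric$per_image_normalization),
          mse = image_mse(images[[i]], images[[j]],
                          metric$per_image_normalization))
        S[i, j] <- S[j, i] <- s
      }
    }
  }
  structure(list(ions = ids, S = S, metric = metric,
                 degenerate = unname(degenerate)),
            class = "similarity_matrix")
}

#' @export
print.similarity_matrix <- function(x, ...) {
  cat(sprintf("<similarity_matrix> %d ions, metric %s\n",
              length(x$ions), x$metric$name))
  print(round(x$S, 3))
  invisible(x)
}

#' Clustering parameters
#'
#' @param threshold score cutoff tau. For similarity metrics an edge is
#'   drawn when the score is `>= tau`; for dissimilarity metrics when it is
#'   `<= tau` (ties inclusive, so the edge rule is a closed condition).
#' @param metric a [metric_spec()].
#' @param patch optional [patch_config()] enabling the coherent
#'   (patch-pooled) SSN variant.
#' @return Object of class `cluster_params`.
#' @export
cluster_params <- function(threshold = 0.90, metric = metric_spec("cosine"),
                           patch = NULL) {
  stopifnot(inherits(metric, "metric_spec"))
  if (!is.numeric(threshold) || length(threshold) != 1L || !is.finite(threshold))
    stop("threshold must be a single finite number")
  if (metric$orientation == "similarity" && threshold < 0)
    stop("a similarity threshold cannot be negative")
  if (metric$orientation == "dissimilarity" && threshold < 0)
    stop("a dissimilarity threshold cannot be negative")
  if (!is.null(patch)) stopifnot(inherits(patch, "patch_config"))
  structure(list(threshold = threshold, metric = metric, patch = patch),
            class = "cluster_params")
}

#' Patch pooling configuration for coherent SSN
#'
#' Non-overlapping `p x p` patch pooling emphasizes regional spatial
#' coherence while suppressing localized (single-pixel) noise. `p = 1`
#' reduces to plain SSN.
#'
#' @param patch_size patch side length in pixels (p >= 1).
#' @param pooling `"mean"` or `"median"`, computed over the valid pixels of
#'   each patch; patches without any valid pixel are masked.
#' @return Object of class `patch_config`.
#' @export
patch_config <- function(patch_size = 4L, pooling = c("mean", "median")) {
  pooling <- match.arg(pooling)
  patch_size <- as.integer(patch_size)
  if (patch_size < 1L) stop("patch_size must be >= 1")
  structure(list(patch_size = patch_size, pooling = pooling),
            class = "patch_config")
}

#' Build the spatial similarity network
#'
#' Nodes are product ions; an undirected edge connects two ions whose
#' spatial similarity passes the threshold rule of `params` (no
#' self-loops). Edge scores are kept as the `score` edge attribute.
#'
#' @param matrix a [similarity_matrix()].
#' @param params a [cluster_params()] whose metric matches the matrix's.
#' @return An undirected `igraph` graph with one vertex per ion.
#' @export
build_ssn_graph <- function(matrix, params = cluster_params()) {
  stopifnot(inherits(matrix, "similarity_matrix"),
            inherits(params, "cluster_params"))
  if (params$metric$name != matrix$metric$name)
    stop("params metric (", params$metric$name,
         ") does not match matrix metric (", matrix$metric$name, ")")
  S <- matrix$S
  k <- nrow(S)
  pass <- if (params$metric$orientation == "similarity") S >= params$threshold
          else S <= params$threshold
  pass[lower.tri(pass, diag = TRUE)] <- FALSE
  idx <- which(pass, arr.ind = TRUE)
  g <- igraph::make_empty_graph(n = k, directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = matrix$ions)
  if (nrow(idx)) {
    g <- igraph::add_edges(g, rbind(idx[, 1L], idx[, 2L]))
    g <- igraph::set_edge_attr(g, "score", value = S[idx])
  }
  attr(g, "ssn_params") <- params
  g
}

#' Cluster the network by connected components
#'
#' Groups of product ions that share the same spatial distribution form the
#' connected components of the SSN graph. Singlets (unclustered ions, e.g.
#' low-S/N ions that fluctuate across pixels) are retained and flagged, not
#' discarded. The result is a partition: every ion belongs to exactly one
#' cluster.
#'
#' @param graph an SSN graph from [build_ssn_graph()].
#' @return Object of class `cluster_set`: `clusters` (list of character
#'   vectors of ion identifiers, largest first), `singlet` (logical per
#'   cluster) and `nodes` (all ion identifiers).
#' @export
ssn_components <- function(graph) {
  comp <- igraph::components(graph)
  nodes <- igraph::V(graph)$name
  clusters <- split(nodes, comp$membership)
  ord <- order(-lengths(clusters),
               vapply(clusters, function(cl) cl[1L], character(1)))
  clusters <- unname(clusters[ord])
  structure(list(clusters = clusters, singlet = lengths(clusters) == 1L,
                 nodes = nodes),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("<cluster_set> %d clusters (%d singlets) over %d ions\n",
              length(x$clusters), sum(x$singlet), length(x$nodes)))
  for (i in seq_along(x$clusters))
    cat(sprintf("  [%d]%s %s\n", i, if (x$singlet[i]) "*" else " ",
                paste(x$clusters[[i]], collapse = ", ")))
  invisible(x)
}

#' Pool an ion image into non-overlapping patches
#'
#' @param image an [ion_image()].
#' @param patch a [patch_config()]; errors if the patch side exceeds both
#'   image dimensions.
#' @return A pooled `ion_image` of shape `ceiling(dim / p)`; each patch
#'   value is the pooling statistic over the patch's valid pixels, and
#'   patches containing no valid pixel are masked invalid.
#' @export
pool_image <- function(image, patch = patch_config()) {
  stopifnot(inherits(image, "ion_image"), inherits(patch, "patch_config"))
  p <- patch$patch_size
  d <- dim(image$values)
  if (p > d[1L] && p > d[2L])
    stop("patch_size ", p, " exceeds both image dimensions (",
         d[1L], " x ", d[2L], ")")
  nr <- ceiling(d[1L] / p); nc <- ceiling(d[2L] / p)
  vals <- matrix(0, nr, nc)
  mask <- matrix(FALSE, nr, nc)
  stat <- if (patch$pooling == "mean") mean else median
  for (i in seq_len(nr)) {
    ri <- seq((i - 1L) * p + 1L, min(i * p, d[1L]))
    for (j in seq_len(nc)) {
      ci <- seq((j - 1L) * p + 1L, min(j * p, d[2L]))
      v <- image$values[ri, ci, drop = FALSE]
      m <- image$valid_mask[ri, ci, drop = FALSE]
      if (any(m)) {
        vals[i, j] <- stat(v[m])
        mask[i, j] <- TRUE
      }
    }
  }
  new_ion_image(vals, mask, image$target_mz, image$tolerance, image$filter)
}

#' Coherent (patch-based) SSN clustering
#'
#' Pools every image into `p x p` patches, then runs the plain pipeline
#' (similarity matrix, graph, connected components) on the pooled images.
#' Pooling suppresses localized noise such as isolated hot pixels, which
#' can otherwise split a true cluster; `p = 1` is identical to plain SSN.
#'
#' @param images list of co-registered [ion_image()]s.
#' @param params a [cluster_params()] with a non-`NULL` `patch`.
#' @return A `cluster_set`.
#' @export
coherent_ssn <- function(images, params) {
  stopifnot(inherits(params, "cluster_params"))
  patch <- if (is.null(params$patch)) patch_config(1L) else params$patch
  pooled <- lapply(images, pool_image, patch = patch)
  names(pooled) <- names(images)
  sm <- similarity_matrix(pooled, params$metric)
  ssn_components(build_ssn_graph(sm, params))
}

#' One-call SSN clustering
#'
#' Convenience wrapper: similarity matrix, graph and components in one
#' step ([coherent_ssn()] when `params$patch` is set).
#'
#' @param images list of co-registered [ion_image()]s.
#' @param params a [cluster_params()].
#' @return A `cluster_set`.
#' @export
ssn_cluster <- function(images, params = cluster_params()) {
  if (!is.null(params$patch) && params$patch$patch_size > 1L)
    return(coherent_ssn(images, params))
  sm <- similarity_matrix(images, params$metric)
  ssn_components(build_ssn_graph(sm, params))
}

#' Deconvoluted cluster spectrum
#'
#' Reassembles the MS2 spectrum of one precursor from its product-ion
#' cluster: one peak per cluster member at the member's target m/z, with
#' intensity equal to the mean image intensity over valid pixels, scaled so
#' the base peak is 100.
#'
#' @param cluster character vector of ion identifiers (one cluster of a
#'   `cluster_set`).
#' @param images the named list of [ion_image()]s the clustering ran on.
#' @return Data frame with columns `mz` and `intensity` (base peak = 100),
#'   sorted by m/z; empty (with attribute `degenerate = TRUE`) for an empty
#'   cluster or all-zero images.
#' @export
cluster_spectrum <- function(cluster, images) {
  empty <- data.frame(mz = numeric(0), intensity = numeric(0))
  if (length(cluster) == 0L) return(structure(empty, degenerate = TRUE))
  if (!all(cluster %in% names(images)))
    stop("cluster members missing from images: ",
         paste(setdiff(cluster, names(images)), collapse = ", "))
  mz <- vapply(images[cluster], function(im) im$target_mz, numeric(1))
  mean_int <- vapply(images[cluster],
                     function(im) mean(im$values[im$valid_mask]), numeric(1))
  if (max(mean_int) == 0) return(structure(empty, degenerate = TRUE))
  out <- data.frame(mz = unname(mz),
                    intensity = 100 * unname(mean_int) / max(mean_int))
  out[order(out$mz), , drop = FALSE]
}

#' Compare a deconvoluted spectrum to a reference standard
#'
#' Both spectra are base-peak normalized; reference peaks below `min_rel`
#' of the base peak are excluded from the denominator (the 1 %-of-base-peak
#' criterion). A reference peak counts as recovered when a deconvoluted
#' peak lies within `mz_tol`.
#'
#' @param decon deconvoluted spectrum, data frame with `mz`, `intensity`.
#' @param reference reference (standard) spectrum, same layout.
#' @param mz_tol m/z matching tolerance (Th).
#' @param min_rel minimum relative intensity (fraction of base peak) for a
#'   reference peak to enter the comparison.
#' @return List: `recovery` (fraction of qualifying reference peaks
#'   recovered; 1 if none qualify), `matched` (data frame of reference m/z,
#'   matched decon m/z), `unmatched_reference`, `extra_decon` (decon peaks
#'   with no reference counterpart).
#' @export
compare_to_reference <- function(decon, reference, mz_tol = 0.3,
                                 min_rel = 0.01) {
  norm <- function(sp) {
    if (nrow(sp) && max(sp$intensity) > 0)
      sp$intensity <- 100 * sp$intensity / max(sp$intensity)
    sp
  }
  decon <- norm(as.data.frame(decon)); reference <- norm(as.data.frame(reference))
  ref <- reference[reference$intensity >= 100 * min_rel, , drop = FALSE]
  if (nrow(ref) == 0L)
    return(list(recovery = 1, matched = data.frame(ref_mz = numeric(0),
                decon_mz = numeric(0)), unmatched_reference = numeric(0),
                extra_decon = decon$mz))
  hit <- vapply(ref$mz, function(m) {
    d <- abs(decon$mz - m)
    if (length(d) && min(d) <= mz_tol) decon$mz[which.min(d)] else NA_real_
  }, numeric(1))
  extra <- decon$mz[vapply(decon$mz, function(m)
    all(abs(reference$mz - m) > mz_tol), logical(1))]
  list(recovery = mean(!is.na(hit)),
       matched = data.frame(ref_mz = ref$mz[!is.na(hit)],
                            decon_mz = hit[!is.na(hit)]),
       unmatched_reference = ref$mz[is.na(hit)],
       extra_decon = extra)
}

#' Jaccard similarity of replicate cluster sets
#'
#' Quantifies SSN reproducibility across replicate datasets. Ions are
#' first matched across sets greedily by nearest m/z within `mz_tol`
#' (numeric inputs) or taken verbatim (character inputs); the n-way Jaccard
#' index is the size of the intersection of all sets over the size of their
#' union. The mean of all pairwise Jaccard indices is reported alongside.
#'
#' @param sets list of two or more clusters, each a numeric vector of ion
#'   m/z values (or a character vector of ion identifiers).
#' @param mz_tol m/z matching tolerance (Th) for numeric inputs.
#' @return Object of class `cluster_comparison`: `jaccard` (n-way),
#'   `pairwise_mean`, `pairwise` (matrix), `shared_ions`, `union_ions`.
#'   Defined as 1 when all sets are empty.
#' @examples
#' # three replicates sharing 17 ions out of a union of 19
#' ions <- 100 + seq_len(19)
#' cluster_jaccard(list(ions[1:18], ions[c(1:17, 19)], ions[1:17]))$jaccard
#' @export
cluster_jaccard <- function(sets, mz_tol = 0.3) {
  if (!is.list(sets) || length(sets) < 2L)
    stop("cluster_jaccard needs at least two cluster sets")
  k <- length(sets)
  if (all(vapply(sets, is.character, logical(1)))) {
    registry <- unique(unlist(sets))
    member <- vapply(sets, function(s) registry %in% s,
                     logical(length(registry)))
  } else {
    sets <- lapply(sets, as.numeric)
    registry <- numeric(0)
    member <- matrix(FALSE, 0L, k)
    for (j in seq_len(k)) {
      claimed <- logical(length(registry))
      for (m in sort(sets[[j]])) {
        d <- abs(registry - m)
        d[claimed] <- Inf
        if (length(d) && min(d) <= mz_tol) {
          i <- which.min(d)
        } else {
          registry <- c(registry, m)
          member <- rbind(member, rep(FALSE, k))
          claimed <- c(claimed, FALSE)
          i <- length(registry)
        }
        member[i, j] <- TRUE
        claimed[i] <- TRUE
      }
    }
  }
  member <- matrix(member, ncol = k)
  n_union <- nrow(member)
  shared <- if (n_union) which(rowSums(member) == k) else integer(0)
  jac <- if (n_union == 0L) 1 else length(shared) / n_union
  pw <- matrix(1, k, k)
  for (i in seq_len(k - 1L)) for (j in seq(i + 1L, k)) {
    u <- sum(member[, i] | member[, j])
    pw[i, j] <- pw[j, i] <- if (u == 0L) 1 else
      sum(member[, i] & member[, j]) / u
  }
  structure(list(jaccard = jac,
                 pairwise_mean = mean(pw[upper.tri(pw)]),
                 pairwise = pw,
                 shared_ions = registry[shared],
                 union_ions = registry),
            class = "cluster_comparison")
}

#' @export
print.cluster_comparison <- function(x, ...) {
  cat(sprintf(
    "<cluster_comparison> n-way Jaccard %.3f (pairwise mean %.3f); %d shared / %d union\n",
    x$jaccard, x$pairwise_mean, length(x$shared_ions), length(x$union_ions)))
  invisible(x)
}

#' Write a cluster set as TSV
#'
#' One row per ion: identifier, cluster id, singlet flag. The inverse of
#' the layout expected by `cluster_jaccard` workflows reading replicate
#' runs back from disk.
#'
#' @param clusters a `cluster_set`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cluster_table <- function(clusters, path) {
  stopifnot(inherits(clusters, "cluster_set"))
  df <- do.call(rbind, lapply(seq_along(clusters$clusters), function(i)
    data.frame(ion = clusters$clusters[[i]], cluster = i,
               singlet = clusters$singlet[i])))
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
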