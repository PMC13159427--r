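# monoisotopic masses of the most abundant isotope (IUPAC 2021), Da
.element_mono <- c(
  H = 1.00782503207, C = 12.0, N = 14.0030740048, O = 15.9949146196,
  P = 30.97376163, S = 31.97207100, Na = 22.9897692809, K = 38.96370668,
  Ag = 106.905097, Cl = 34.96885268, F = 18.99840322, Br = 78.9183371,
  I = 126.904473, Si = 27.9769265325, Se = 73.9224764, Fe = 55.9349375,
  Ca = 39.96259098, Mg = 23.9850417, Li = 7.01600455, Zn = 63.9291422)

.electron_mass <- 0.00054857990907

#' Monoisotopic mass of an elemental formula
#'
#' Sum of most-abundant-isotope masses, for Hill-style formulas with
#' integer counts (no parentheses or charges). Used to derive library
#' precursor m/z values from neutral formulas.
#'
#' @param formula e.g. `"C42H82NO8P"`; an empty string has mass 0.
#' @return Monoisotopic mass in Da.
#' @examples
#' monoisotopic_mass("H2O")            # 18.0106
#' monoisotopic_mass("C42H82NO8P")     # neutral PC(34:1)
#' @export
monoisotopic_mass <- function(formula) {
  if (!is.character(formula) || length(formula) != 1L)
    stop("formula must be a single string")
  formula <- trimws(formula)
  if (formula == "") return(0)
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
  toks <- regmatches(formula, list(m))[[1]]
  if (sum(nchar(toks)) != nchar(formula))
    stop("cannot parse formula: ", formula)
  total <- 0
  for (t in toks) {
    el <- sub("[0-9]*$", "", t)
    cnt <- sub("^[A-Za-z]+", "", t)
    cnt <- if (cnt == "") 1L else as.integer(cnt)
    if (!el %in% names(.element_mono))
      stop("unknown element '", el, "' in formula ", formula)
    total <- total + .element_mono[[el]] * cnt
  }
  total
}

#' Adduct definition
#'
#' Mass shift of a singly charged cationic adduct, electron mass included
#' (e.g. `+H` is +1.007276 Da, a proton, not a hydrogen atom). Built-in
#' adducts: `+H`, `+Na`, `+K`, `+Ag`, `+NH4`.
#'
#' @param name adduct name; a built-in name fills `mass_shift`.
#' @param mass_shift monoisotopic shift in Da (required for custom names).
#' @param charge currently only +1 supported.
#' @return Object of class `adduct_def`.
#' @export
adduct_def <- function(name, mass_shift = NULL, charge = 1L) {
  builtin <- c("+H" = .element_mono[["H"]] - .electron_mass,
               "+Na" = .element_mono[["Na"]] - .electron_mass,
               "+K" = .element_mono[["K"]] - .electron_mass,
               "+Ag" = .element_mono[["Ag"]] - .electron_mass,
               "+NH4" = .element_mono[["N"]] + 4 * .element_mono[["H"]] -
                 .electron_mass)
  if (is.null(mass_shift)) {
    if (!name %in% names(builtin))
      stop("unknown adduct '", name, "'; supply mass_shift explicitly")
    mass_shift <- builtin[[name]]
  }
  if (!is.finite(mass_shift)) stop("mass_shift must be finite")
  if (as.integer(charge) != 1L) stop("only +1 adducts are supported")
  structure(list(name = name, mass_shift = mass_shift, charge = 1L),
            class = "adduct_def")
}

#' Adduct m/z from a neutral mass
#'
#' @param neutral_mass monoisotopic neutral mass (Da), > 0.
#' @param adduct an [adduct_def()] or built-in adduct name.
#' @return `(neutral_mass + mass_shift) / charge` in Th.
#' @examples
#' adduct_mz(monoisotopic_mass("C42H82NO8P"), "+Na")  # ~782.57
#' @export
adduct_mz <- function(neutral_mass, adduct) {
  if (is.character(adduct)) adduct <- adduct_def(adduct)
  stopifnot(inherits(adduct, "adduct_def"))
  if (neutral_mass <= 0) stop("neutral_mass must be positive")
  (neutral_mass + adduct$mass_shift) / adduct$charge
}

#' Build a product-ion library
#'
#' In-memory constructor for the annotation reference: one row per
#' species-adduct with its neutral formula, diagnostic product ions, and a
#' precursor m/z derived from the formula and adduct. If `precursor_mz` is
#' supplied it is checked against the derived value (1e-4 Th).
#'
#' @param species species shorthand, e.g. `"PC(18:0_18:2)"`.
#' @param formula neutral elemental formula per species.
#' @param adduct adduct name per species (see [adduct_def()]).
#' @param diagnostic_mz list of numeric vectors of diagnostic product-ion
#'   m/z values (nonempty).
#' @param class lipid/compound class label.
#' @param diagnostic_label optional list of character vectors naming each
#'   diagnostic ion.
#' @param precursor_mz optional expected precursor m/z for validation.
#' @return Data frame of class `ion_library` with list columns
#'   `diagnostic_mz`, `diagnostic_label` and derived `precursor_mz`.
#' @export
ion_library <- function(species, formula, adduct, diagnostic_mz,
                        class = NA_character_, diagnostic_label = NULL,
                        precursor_mz = NULL) {
  n <- length(species)
  stopifnot(length(formula) == n, length(adduct) == n,
            length(diagnostic_mz) == n)
  if (any(lengths(diagnostic_mz) == 0L))
    stop("every library entry needs at least one diagnostic ion")
  derived <- mapply(function(f, a) adduct_mz(monoisotopic_mass(f), a),
                    formula, adduct)
  if (!is.null(precursor_mz)) {
    bad <- abs(precursor_mz - derived) > 1e-4
    if (any(bad))
      stop("precursor_mz inconsistent with formula+adduct for: ",
           paste(species[bad], collapse = ", "))
  }
  if (is.null(diagnostic_label))
    diagnostic_label <- lapply(diagnostic_mz, function(z) rep(NA_character_,
                                                              length(z)))
  out <- data.frame(species = species, formula = formula, adduct = adduct,
                    class = rep_len(class, n),
                    precursor_mz = unname(derived),
                    stringsAsFactors = FALSE)
  out$diagnostic_mz <- diagnostic_mz
  out$diagnostic_label <- diagnostic_label
  structure(out, class = c("ion_library", "data.frame"))
}

#' Read a product-ion library from TSV
#'
#' Expected columns: `species`, `formula`, `adduct`, `class`,
#' `diagnostic_mzs` (semicolon-separated m/z values) and optionally
#' `diagnostic_labels` (semicolon-separated) and `precursor_mz` (validated
#' against the formula-derived value on load).
#'
#' @param path TSV path.
#' @return An `ion_library`.
#' @export
read_ion_library <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("species", "formula", "adduct", "diagnostic_mzs")
  if (!all(need %in% names(df)))
    stop("library is missing columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  dmz <- lapply(strsplit(df$diagnostic_mzs, ";"), as.numeric)
  dlab <- if ("diagnostic_labels" %in% names(df))
    strsplit(df$diagnostic_labels, ";") else NULL
  ion_library(df$species, df$formula, df$adduct, dmz,
              class = if ("class" %in% names(df)) df$class else NA_character_,
              diagnostic_label = dlab,
              precursor_mz = if ("precursor_mz" %in% names(df))
                df$precursor_mz else NULL)
}

#' Write a product-ion library as TSV
#'
#' @param library an [ion_library()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ion_library <- function(library, path) {
  stopifnot(inherits(library, "ion_library"))
  df <- data.frame(
    species = library$species, formula = library$formula,
    adduct = library$adduct, class = library$class,
    precursor_mz = library$precursor_mz,
    diagnostic_mzs = vapply(library$diagnostic_mz, paste, character(1),
                            collapse = ";"),
    diagnostic_labels = vapply(library$diagnostic_label, paste, character(1),
                               collapse = ";"))
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Match FT peaks in an isolation window against library precursors
#'
#' Restricts the FT peak list to the isolation window (center +/- width/2)
#' and reports, for each peak, every library precursor within `ppm_tol`,
#' ranked by absolute ppm error. This is how molecular formulas are
#' assigned from the accurate mass measured by FTMS; the default 3 ppm
#' separates isobars a 0.7 Da window co-isolates.
#'
#' @param ft_peaks FT peak matrix (columns mz, intensity).
#' @param window an MS2 [scan_filter()] defining the isolation window.
#' @param library an [ion_library()].
#' @param ppm_tol matching tolerance in ppm.
#' @return Data frame: `peak_mz`, `species`, `adduct`, `precursor_mz`,
#'   `ppm`, ordered by peak then |ppm| (possibly zero rows).
#' @export
match_precursor <- function(ft_peaks, window, library, ppm_tol = 3) {
  stopifnot(inherits(window, "scan_filter"), inherits(library, "ion_library"))
  if (window$ms_level < 2L)
    stop("window must be an MS2 scan filter with an isolation window")
  validate_peaks(ft_peaks, "ft_peaks")
  half <- window$isolation_width / 2
  inwin <- abs(ft_peaks[, 1L] - window$isolation_center) <= half
  out <- list()
  for (m in ft_peaks[inwin, 1L]) {
    ppm <- (m - library$precursor_mz) / library$precursor_mz * 1e6
    hit <- which(abs(ppm) <= ppm_tol)
    if (length(hit)) {
      hit <- hit[order(abs(ppm[hit]))]
      out[[length(out) + 1L]] <- data.frame(
        peak_mz = m, species = library$species[hit],
        adduct = library$adduct[hit],
        precursor_mz = library$precursor_mz[hit], ppm = ppm[hit])
    }
  }
  if (!length(out))
    return(data.frame(peak_mz = numeric(0), species = character(0),
                      adduct = character(0), precursor_mz = numeric(0),
                      ppm = numeric(0)))
  do.call(rbind, out)
}

#' Match a product-ion cluster against one library entry
#'
#' Greedy nearest-m/z matching between the cluster's ions and the entry's
#' diagnostic ions, each ion used at most once.
#'
#' @param cluster_mz numeric vector of cluster ion m/z values.
#' @param entry one row of an [ion_library()] (or a list with
#'   `diagnostic_mz`).
#' @param mz_tol matching tolerance (Th).
#' @return List: `matched_diag` (diagnostic ions with a cluster partner),
#'   `total_diag`, `cluster_explained` (fraction of cluster ions the entry
#'   accounts for; 0 for an empty cluster).
#' @export
match_cluster <- function(cluster_mz, entry, mz_tol = 0.3) {
  if (mz_tol <= 0) stop("mz_tol must be positive")
  diag_mz <- if (is.data.frame(entry)) entry$diagnostic_mz[[1L]]
             else entry$diagnostic_mz
  diag_mz <- as.numeric(diag_mz)
  total <- length(diag_mz)
  nc <- length(cluster_mz)
  if (nc == 0L || total == 0L)
    return(list(matched_diag = 0L, total_diag = total, cluster_explained = 0))
  pairs <- expand.grid(d = seq_len(total), c = seq_len(nc))
  pairs$delta <- abs(diag_mz[pairs$d] - cluster_mz[pairs$c])
  pairs <- pairs[pairs$delta <= mz_tol, , drop = FALSE]
  pairs <- pairs[order(pairs$delta), , drop = FALSE]
  used_d <- logical(total); used_c <- logical(nc); matched <- 0L
  for (i in seq_len(nrow(pairs))) {
    d <- pairs$d[i]; cc <- pairs$c[i]
    if (!used_d[d] && !used_c[cc]) {
      used_d[d] <- used_c[cc] <- TRUE
      matched <- matched + 1L
    }
  }
  list(matched_diag = matched, total_diag = total,
       cluster_explained = matched / nc)
}

#' Annotate SSN clusters against a product-ion library
#'
#' Scores every (cluster, library entry) pair with [match_cluster()] and,
#' when FT peaks and the isolation window are supplied, attaches the
#' precursor ppm error from [match_precursor()]. Candidates are ranked per
#' cluster by the lexicographic key (fraction of diagnostics matched,
#' fraction of cluster explained, -|ppm|); ties on the full key are
#' reported via the `tie` flag, not broken silently.
#'
#' @param clusters a `cluster_set` (ion identifiers parseable as m/z) or a
#'   list of numeric m/z vectors.
#' @param library an [ion_library()].
#' @param ft_peaks optional FT peak matrix for accurate-mass evidence.
#' @param window optional MS2 [scan_filter()] (required with `ft_peaks`).
#' @param mz_tol MS2 matching tolerance (Th).
#' @param ppm_tol FT precursor tolerance (ppm).
#' @param min_matched minimum diagnostic matches for a candidate to be
#'   reported.
#' @return Data frame of class `cluster_annotation`: one row per retained
#'   (cluster, candidate): `cluster`, `species`, `adduct`, `matched_diag`,
#'   `total_diag`, `cluster_explained`, `precursor_ppm`, `rank`, `tie`.
#' @export
annotate_clusters <- function(clusters, library, ft_peaks = NULL,
                              window = NULL, mz_tol = 0.3, ppm_tol = 3,
                              min_matched = 1L) {
  stopifnot(inherits(library, "ion_library"))
  cl <- if (inherits(clusters, "cluster_set"))
    lapply(clusters$clusters, function(x) as.numeric(x)) else clusters
  prec <- NULL
  if (!is.null(ft_peaks)) {
    if (is.null(window))
      stop("window is required when ft_peaks are supplied")
    prec <- match_precursor(ft_peaks, window, library, ppm_tol)
  }
  rows <- list()
  for (ci in seq_along(cl)) {
    cand <- list()
    for (li in seq_len(nrow(library))) {
      m <- match_cluster(cl[[ci]], library[li, ], mz_tol)
      if (m$matched_diag < min_matched) next
      ppm <- NA_real_
      if (!is.null(prec)) {
        hit <- prec[prec$species == library$species[li] &
                      prec$adduct == library$adduct[li], , drop = FALSE]
        if (nrow(hit)) ppm <- hit$ppm[which.min(abs(hit$ppm))]
      }
      cand[[length(cand) + 1L]] <- data.frame(
        cluster = ci, species = library$species[li],
        adduct = library$adduct[li], matched_diag = m$matched_diag,
        total_diag = m$total_diag, cluster_explained = m$cluster_explained,
        precursor_ppm = ppm)
    }
    if (!length(cand)) next
    cand <- do.call(rbind, cand)
    frac <- cand$matched_diag / cand$total_diag
    ppmkey <- ifelse(is.na(cand$precursor_ppm), Inf, abs(cand$precursor_ppm))
    ord <- order(-frac, -cand$cluster_explained, ppmkey)
    cand <- cand[ord, , drop = FALSE]
    key <- paste(frac[ord], cand$cluster_explained,
                 signif(ppmkey[ord], 10))
    cand$rank <- seq_len(nrow(cand))
    cand$tie <- duplicated(key) | duplicated(key, fromLast = TRUE)
    rows[[length(rows) + 1L]] <- cand
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(cluster = integer(0), species = character(0),
               adduct = character(0), matched_diag = integer(0),
               total_diag = integer(0), cluster_explained = numeric(0),
               precursor_ppm = numeric(0), rank = integer(0),
               tie = logical(0))
  rownames(out) <- NULL
  structure(out, class = c("cluster_annotation", "data.frame"))
}

#' Assign an MSI annotation confidence level
#'
#' Five-level scale for molecular annotation in mass spectrometry imaging.
#' Level 5: accurate mass only. Level 3: accurate mass plus MS2 data from a
#' few pixels. Level 2: fragmentation at all pixels, product-ion clustering
#' above the similarity threshold, and a library match. Level 1: Level-2
#' evidence confirmed against a reference standard with orthogonal
#' validation. Level 4 is never auto-assigned: it is only reachable through
#' a user-supplied rubric function.
#'
#' @param accurate_mass accurate-mass (FTMS) evidence; required for any
#'   level.
#' @param ms2_some_pixels MS2 spectra from at least a few pixels.
#' @param ms2_all_pixels MS2 spectra at every pixel (implies
#'   `ms2_some_pixels`; the reverse inconsistency is an error).
#' @param cluster_above_threshold product ions cluster with spatial
#'   similarity above the defined threshold.
#' @param library_match cluster matched in the product-ion library.
#' @param standard_confirmed spectrum confirmed against a reference
#'   standard.
#' @param orthogonal_validation independent orthogonal evidence.
#' @param level4_rule optional function of the named flag list returning
#'   `TRUE` to assign Level 4 where Levels 1-3 do not apply.
#' @return Integer confidence level in 1..5.
#' @examples
#' assign_confidence(accurate_mass = TRUE)                       # 5
#' assign_confidence(TRUE, ms2_some_pixels = TRUE)               # 3
#' assign_confidence(TRUE, TRUE, TRUE, TRUE, TRUE)               # 2
#' @export
assign_confidence <- function(accurate_mass = FALSE, ms2_some_pixels = FALSE,
                              ms2_all_pixels = FALSE,
                              cluster_above_threshold = FALSE,
                              library_match = FALSE,
                              standard_confirmed = FALSE,
                              orthogonal_validation = FALSE,
                              level4_rule = NULL) {
  flags <- list(accurate_mass = isTRUE(accurate_mass),
                ms2_some_pixels = isTRUE(ms2_some_pixels),
                ms2_all_pixels = isTRUE(ms2_all_pixels),
                cluster_above_threshold = isTRUE(cluster_above_threshold),
                library_match = isTRUE(library_match),
                standard_confirmed = isTRUE(standard_confirmed),
                orthogonal_validation = isTRUE(orthogonal_validation))
  if (flags$ms2_all_pixels && !flags$ms2_some_pixels)
    stop("inconsistent flags: ms2_all_pixels implies ms2_some_pixels")
  if (!flags$accurate_mass)
    stop("the confidence scale is anchored on accurate mass; ",
         "accurate_mass evidence is required")
  level2 <- flags$ms2_all_pixels && flags$cluster_above_threshold &&
    flags$library_match
  if (level2 && flags$standard_confirmed && flags$orthogonal_validation)
    return(1L)
  if (level2) return(2L)
  if (!is.null(level4_rule) && isTRUE(level4_rule(flags))) return(4L)
  if (flags$ms2_some_pixels) return(3L)
  5L
}

#' Demo phospholipid product-ion library
#'
#' Small rule-derived library for the sodiated/protonated PC species used
#' throughout the examples and the synthetic phantom: head-group losses
#' (-59, trimethylamine; -183, phosphocholine) and sodiated acyl-chain
#' losses for PC+Na, plus the m/z 184.1 phosphocholine ion for PC+H. It is
#' a synthetic fixture for demonstration, not a curated reference library.
#'
#' @return An [ion_library()] with the isobar triplet co-isolated near
#'   m/z 808.6 and the PC(34:1)+Na standard.
#' @export
demo_library <- function() {
  ion_library(
    species = c("PC(18:0_18:2)", "PC(18:1_18:1)", "PC(38:5)", "PC(O-36:3)",
                "PC(16:0_18:1)"),
    formula = c("C44H84NO8P", "C44H84NO8P", "C46H82NO8P", "C44H84NO7P",
                "C42H82NO8P"),
    adduct = c("+Na", "+Na", "+H", "+K", "+Na"),
    class = c("PC", "PC", "PC", "PC-O", "PC"),
    diagnostic_mz = list(
      c(465.3, 469.3, 749.5, 625.5),   # sodiated acyl losses + -59/-183
      c(467.3, 749.5, 625.5),
      c(184.1, 625.5, 549.5),
      c(146.9, 625.6, 565.5),
      c(441.3, 459.3, 723.5, 599.5)),
    diagnostic_label = list(
      c("loss FA18:2 as Na salt", "loss FA18:0 as Na salt", "-N(CH3)3",
        "-phosphocholine"),
      c("loss FA18:1 as Na salt", "-N(CH3)3", "-phosphocholine"),
      c("phosphocholine head", "-183", "loss FA18:2"),
      c("K head marker", "-183+K", "loss O-alkyl"),
      c("loss FA18:1 as Na salt", "loss FA16:0 as Na salt", "-N(CH3)3",
        "-phosphocholine")))
}
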