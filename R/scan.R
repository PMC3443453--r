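#' Enumerate marker pairs from a marker map
#'
#' Builds the pair list for a genome scan: syntenic (within-chromosome)
#' pairs carry their physical distance in bp; non-syntenic
#' (between-chromosome) pairs have no distance. Pairs on unmapped markers
#' are never enumerated. Optional distance capping (syntenic mode) and
#' seeded uniform subsampling keep large panels tractable; the total number
#' of pairs before subsampling is recorded so proportions remain estimable.
#'
#' @param map marker map data.frame (`marker_id`, `chrom`, `pos_bp`), e.g.
#'   from [markerMap()]; assumed position-sorted within chromosome (the
#'   [GenotypePanel()] constructor guarantees this).
#' @param mode `"syntenic"`, `"nonsyntenic"` or `"both"`.
#' @param maxDistanceBp optional cap on syntenic pair distance.
#' @param subsample optional number of pairs to keep (uniform, seeded).
#' @param seed RNG seed used when subsampling.
#' @return data.frame with `i`, `j` (column indices into the map),
#'   `marker_i`, `marker_j`, `chrom_i`, `chrom_j`, `distance_bp` (NA when
#'   non-syntenic) and `syntenic`; attribute `n_enumerated` gives the pair
#'   count before subsampling.
#' @export
enumeratePairs <- function(map, mode = c("syntenic", "nonsyntenic", "both"),
                           maxDistanceBp = NULL, subsample = NULL, seed = NULL) {
  mode <- match.arg(mode)
  if (nrow(map) < 2) stop("need at least two markers")
  mapped <- which(map$chrom != "unknown" & !is.na(map$pos_bp))
  chrom <- map$chrom[mapped]
  pos <- map$pos_bp[mapped]
  pieces <- list()
  if (mode %in% c("syntenic", "both")) {
    for (ch in unique(chrom)) {
      idx <- mapped[chrom == ch]
      if (length(idx) < 2) next
      cmb <- utils::combn(seq_along(idx), 2)
      i <- idx[cmb[1, ]]; j <- idx[cmb[2, ]]
      d <- abs(map$pos_bp[j] - map$pos_bp[i])
      keep <- if (is.null(maxDistanceBp)) TRUE else d <= maxDistanceBp
      pieces[[length(pieces) + 1L]] <-
        data.frame(i = i[keep], j = j[keep], distance_bp = d[keep],
                   syntenic = TRUE)
    }
  }
  if (mode %in% c("nonsyntenic", "both")) {
    chs <- unique(chrom)
    n_cross <- 0
    counts <- table(chrom)
    if (length(chs) >= 2) {
      tot <- sum(counts)
      n_cross <- (tot^2 - sum(counts^2)) / 2
      if (n_cross > 5e7)
        stop("non-syntenic enumeration would produce > 5e7 pairs; subsample a smaller map")
      for (a in seq_along(chs)[-length(chs)]) for (b in seq((a + 1), length(chs))) {
        ia <- mapped[chrom == chs[a]]; ib <- mapped[chrom == chs[b]]
        g <- expand.grid(i = ia, j = ib)
        pieces[[length(pieces) + 1L]] <-
          data.frame(i = pmin(g$i, g$j), j = pmax(g$i, g$j),
                     distance_bp = NA_real_, syntenic = FALSE)
      }
    }
  }
  if (!length(pieces)) stop("no pairs enumerated (check mode and map)")
  out <- do.call(rbind, pieces)
  n_enum <- nrow(out)
  if (!is.null(subsample) && subsample < n_enum) {
    if (!is.null(seed)) set.seed(seed)
    out <- out[sort(sample.int(n_enum, subsample)), , drop = FALSE]
  }
  out$marker_i <- map$marker_id[out$i]
  out$marker_j <- map$marker_id[out$j]
  out$chrom_i <- map$chrom[out$i]
  out$chrom_j <- map$chrom[out$j]
  rownames(out) <- NULL
  attr(out, "n_enumerated") <- n_enum
  attr(out, "subsample_seed") <- seed
  out
}

#' Genome scan: estimate and test all disequilibria for many marker pairs
#'
#' Runs the full [pairDiseq()] hierarchy over a pair list, vectorized: the
#' nine unphased genotype cell counts for every pair are obtained by cross
#' products of per-dosage indicator matrices (missing calls drop out of a
#' pair automatically, so each pair uses its pairwise-complete n), then all
#' estimators, EM gametic LD, delta-method variances, chi-squares and phi2
#' values are computed column-wise. Per-pair degeneracies (monomorphic in
#' the complete cases, flat EM likelihood) are flagged, never fatal.
#'
#' @param panel a (QC-filtered) [GenotypePanel-class].
#' @param pairs pair list from [enumeratePairs()]; default enumerates
#'   according to `mode` and `maxDistanceBp`.
#' @param mode,maxDistanceBp,subsample,seed passed to [enumeratePairs()]
#'   when `pairs` is NULL.
#' @param minN pairs with fewer pairwise-complete animals are flagged
#'   (`low_n`) and their sampling-based columns set to NA.
#' @param emTol,emMaxIter EM controls.
#' @param zygotic which double homozygote defines zygotic LD; see
#'   [pairDiseq()].
#' @return data.frame with one row per pair: the pair key columns, `n`, all
#'   estimates, variances, `x2_*`, `phi2_*` and flags. Suitable for
#'   [binByDistance()], [linkedUnlinkedSummary()], [mafClassSummary()],
#'   [powerVsDistanceCurve()] and for writing with [writePairResults()].
#' @export
scanPairs <- function(panel, pairs = NULL, mode = "syntenic",
                      maxDistanceBp = NULL, subsample = NULL, seed = NULL,
                      minN = 10L, emTol = 1e-10, emMaxIter = 1000L,
                      zygotic = c("designated", "opposite")) {
  stopifnot(is(panel, "GenotypePanel"))
  if (is.null(pairs))
    pairs <- enumeratePairs(markerMap(panel), mode = mode,
                            maxDistanceBp = maxDistanceBp,
                            subsample = subsample, seed = seed)
  d <- dosages(panel)
  m <- ncol(d)
  ind <- lapply(0:2, function(x) {
    M <- matrix(0, nrow(d), m)
    M[which(d == x)] <- 1
    M
  })
  P <- nrow(pairs)
  cells <- matrix(0, P, 9L, dimnames = list(NULL, .CELL_NAMES))
  ij <- cbind(pairs$i, pairs$j)
  if (as.double(m)^2 <= 40 * P || m <= 512) {
    for (x in 0:2) for (y in 0:2) {
      Cxy <- crossprod(ind[[x + 1L]], ind[[y + 1L]])
      cells[, .CELL_NAMES == paste0("g", x, y)] <- Cxy[ij]
    }
  } else {
    for (x in 0:2) for (y in 0:2) {
      cells[, .CELL_NAMES == paste0("g", x, y)] <-
        colSums(ind[[x + 1L]][, pairs$i, drop = FALSE] *
                  ind[[y + 1L]][, pairs$j, drop = FALSE])
    }
  }
  n <- rowSums(cells)
  bad_n <- n < minN
  n_safe <- pmax(n, 1)
  res <- .pairEngine(cells / n_safe, n_safe, emTol = emTol,
                     emMaxIter = emMaxIter, zygotic = zygotic)
  res$n <- as.integer(round(n))
  res$low_n <- bad_n
  if (any(bad_n)) {
    sampling_cols <- grep("^(var_|x2_|phi2_)", names(res), value = TRUE)
    res[bad_n, sampling_cols] <- NA_real_
  }
  key <- pairs[, c("marker_i", "marker_j", "chrom_i", "chrom_j",
                   "distance_bp", "syntenic")]
  out <- cbind(key, res, row.names = NULL)
  attr(out, "n_enumerated") <- attr(pairs, "n_enumerated")
  out
}

#' Write scan rows to a tab-delimited file
#'
#' @param rows scan result from [scanPairs()].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
writePairResults <- function(rows, path) {
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
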