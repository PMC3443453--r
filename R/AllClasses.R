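#' GenotypePanel: unphased diploid dosages plus a marker map
#'
#' The raw observable for all downstream analyses: an animals x markers
#' matrix of allele dosages (copies of the designated A allele, coded 0, 1,
#' 2 or `NA` for missing) together with a marker map giving the chromosome
#' and base-pair position of every marker. Markers are stored sorted by
#' chromosome and position; markers without a known position carry
#' chromosome `"unknown"` and `NA` position.
#'
#' @slot dosages integer matrix, rows = animals (rownames are animal ids),
#'   columns = markers (colnames are marker ids); entries in {0,1,2,NA}.
#' @slot map data.frame with columns `marker_id`, `chrom`, `pos_bp`, one row
#'   per marker, aligned 1:1 with the columns of `dosages`.
#' @slot metadata list of free-form provenance (e.g. which allele was taken
#'   as A at each marker, simulation parameters, QC history).
#'
#' @seealso [GenotypePanel()] for the constructor, [qcFilter()],
#'   [scanPairs()].
#' @export
setClass("GenotypePanel",
  representation(dosages = "matrix", map = "data.frame", metadata = "list"),
  prototype(metadata = list())
)

setValidity("GenotypePanel", function(object) {
  d <- object@dosages
  m <- object@map
  msgs <- character()
  if (!is.numeric(d)) msgs <- c(msgs, "dosages must be a numeric matrix")
  bad <- d[!is.na(d)]
  if (length(bad) && !all(bad %in% c(0, 1, 2)))
    msgs <- c(msgs, "non-missing dosages must be 0, 1 or 2")
  if (is.null(colnames(d))) msgs <- c(msgs, "dosages must have marker ids as colnames")
  if (is.null(rownames(d))) msgs <- c(msgs, "dosages must have animal ids as rownames")
  need <- c("marker_id", "chrom", "pos_bp")
  if (!all(need %in% names(m))) {
    msgs <- c(msgs, sprintf("map must have columns %s", paste(need, collapse = ", ")))
  } else {
    if (nrow(m) != ncol(d)) msgs <- c(msgs, "map rows must match dosage columns")
    else if (!identical(as.character(m$marker_id), colnames(d)))
      msgs <- c(msgs, "map$marker_id must align with colnames(dosages)")
    if (anyDuplicated(m$marker_id)) msgs <- c(msgs, "duplicate marker ids")
    pos <- m$pos_bp[!is.na(m$pos_bp)]
    if (length(pos) && any(pos < 0)) msgs <- c(msgs, "positions must be non-negative")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a GenotypePanel
#'
#' Builds and validates a [GenotypePanel-class] from a dosage matrix and a
#' marker map. Markers are reordered by chromosome then position (unknown
#' positions last), so column order after construction is canonical.
#'
#' @param dosages numeric/integer matrix of 0/1/2/NA dosages, animals in
#'   rows, markers in columns, with row and column names.
#' @param map data.frame with `marker_id`, `chrom`, `pos_bp`. Markers in
#'   `dosages` that are absent from `map` get chromosome `"unknown"`.
#' @param metadata optional list.
#' @return A `GenotypePanel`.
#' @examples
#' d <- matrix(c(0L, 1L, 2L, NA), 2, 2,
#'             dimnames = list(c("an1", "an2"), c("m1", "m2")))
#' map <- data.frame(marker_id = c("m1", "m2"), chrom = "1",
#'                   pos_bp = c(100L, 200L))
#' GenotypePanel(d, map)
#' @export
GenotypePanel <- function(dosages, map, metadata = list()) {
  storage.mode(dosages) <- "integer"
  map$marker_id <- as.character(map$marker_id)
  map$chrom <- as.character(map$chrom)
  missing_markers <- setdiff(colnames(dosages), map$marker_id)
  if (length(missing_markers)) {
    map <- rbind(map[, c("marker_id", "chrom", "pos_bp")],
                 data.frame(marker_id = missing_markers, chrom = "unknown",
                            pos_bp = NA_integer_))
  }
  extra <- setdiff(map$marker_id, colnames(dosages))
  if (length(extra))
    stop("map contains markers absent from the dosage matrix: ",
         paste(head(extra, 5), collapse = ", "))
  map <- map[order(map$chrom, map$pos_bp, map$marker_id, na.last = TRUE), , drop = FALSE]
  rownames(map) <- NULL
  dosages <- dosages[, map$marker_id, drop = FALSE]
  new("GenotypePanel", dosages = dosages, map = map, metadata = metadata)
}

#' QCReport: bookkeeping of marker quality-control removals
#'
#' Records how many markers each QC rule removed, with each marker counted
#' once under the first rule that removed it (rules are applied in order:
#' monomorphic, unmapped, sex chromosome, MAF, HWD chi-square).
#'
#' @slot nInput number of markers before filtering.
#' @slot removed named integer vector of removal counts per rule.
#' @slot nRetained number of markers kept.
#' @seealso [qcFilter()]
#' @export
setClass("QCReport",
  representation(nInput = "integer", removed = "integer", nRetained = "integer"))

setValidity("QCReport", function(object) {
  if (object@nInput - sum(object@removed) != object@nRetained)
    "removal counts must sum to nInput - nRetained" else TRUE
})
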