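#' @describeIn GenotypePanel-class dosage matrix accessor
#' @param object,x a `GenotypePanel`
#' @export
setGeneric("dosages", function(object) standardGeneric("dosages"))

#' @rdname GenotypePanel-class
#' @export
setMethod("dosages", "GenotypePanel", function(object) object@dosages)

#' @describeIn GenotypePanel-class marker map accessor
#' @export
setGeneric("markerMap", function(object) standardGeneric("markerMap"))

#' @rdname GenotypePanel-class
#' @export
setMethod("markerMap", "GenotypePanel", function(object) object@map)

#' @describeIn GenotypePanel-class animal identifiers
#' @export
setGeneric("animalIds", function(object) standardGeneric("animalIds"))

#' @rdname GenotypePanel-class
#' @export
setMethod("animalIds", "GenotypePanel", function(object) rownames(object@dosages))

#' @describeIn GenotypePanel-class marker identifiers
#' @export
setGeneric("markerIds", function(object) standardGeneric("markerIds"))

#' @rdname GenotypePanel-class
#' @export
setMethod("markerIds", "GenotypePanel", function(object) colnames(object@dosages))

#' @describeIn GenotypePanel-class number of animals
#' @export
setGeneric("nAnimals", function(object) standardGeneric("nAnimals"))

#' @rdname GenotypePanel-class
#' @export
setMethod("nAnimals", "GenotypePanel", function(object) nrow(object@dosages))

#' @describeIn GenotypePanel-class number of markers
#' @export
setGeneric("nMarkers", function(object) standardGeneric("nMarkers"))

#' @rdname GenotypePanel-class
#' @export
setMethod("nMarkers", "GenotypePanel", function(object) ncol(object@dosages))

#' @rdname GenotypePanel-class
#' @param i animal subscript (ids, indices or logical)
#' @param j marker subscript
#' @param ... ignored
#' @param drop ignored (subsetting always returns a panel)
#' @export
setMethod("[", "GenotypePanel", function(x, i, j, ..., drop = FALSE) {
  d <- x@dosages
  if (missing(i)) i <- seq_len(nrow(d))
  if (missing(j)) j <- seq_len(ncol(d))
  d <- d[i, j, drop = FALSE]
  map <- x@map[match(colnames(d), x@map$marker_id), , drop = FALSE]
  rownames(map) <- NULL
  new("GenotypePanel", dosages = d, map = map, metadata = x@metadata)
})

setMethod("show", "GenotypePanel", function(object) {
  map <- object@map
  chroms <- unique(map$chrom)
  n_miss <- sum(is.na(object@dosages))
  cat(sprintf("GenotypePanel: %d animals x %d markers\n",
              nrow(object@dosages), ncol(object@dosages)))
  cat(sprintf("  chromosomes: %s\n",
              paste(head(chroms, 8), collapse = ", ")),
      if (length(chroms) > 8) sprintf("  (+%d more)\n", length(chroms) - 8) else "",
      sep = "")
  cat(sprintf("  missing dosage entries: %d (%.2f%%)\n", n_miss,
              100 * n_miss / length(object@dosages)))
  invisible(NULL)
})

setMethod("show", "QCReport", function(object) {
  cat(sprintf("QCReport: %d markers in, %d retained\n",
              object@nInput, object@nRetained))
  for (nm in names(object@removed))
    cat(sprintf("  removed (%s): %d\n", nm, object@removed[[nm]]))
  invisible(NULL)
})

#' Turn a QCReport into a one-row data.frame
#'
#' @param x a [QCReport-class]
#' @param row.names,optional,... passed for S3 compatibility, ignored.
#' @return one-row data.frame with input, per-rule removal and retained counts.
#' @export
as.data.frame.QCReport <- function(x, row.names = NULL, optional = FALSE, ...) {
  out <- c(n_input = x@nInput, as.list(x@removed), n_retained = x@nRetained)
  as.data.frame(out)
}
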