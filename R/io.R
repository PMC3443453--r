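#' Read a dosage table and marker map
#'
#' The dosage table is tab-delimited with a header row: first column the
#' animal id, remaining columns one marker each, entries 0/1/2 (copies of
#' the designated A allele) or the missing token. The companion map is
#' tab-delimited with columns `marker_id`, `chrom`, `pos_bp`; markers absent
#' from the map are loaded with chromosome `"unknown"`.
#'
#' @param path dosage table path.
#' @param mapPath marker map path, or `NULL` to leave every marker unmapped.
#' @param missingCode token encoding a missing genotype (default `"NA"`).
#' @return a [GenotypePanel-class].
#' @export
readDosageTable <- function(path, mapPath = NULL, missingCode = "NA") {
  tab <- read.delim(path, header = TRUE, sep = "\t", colClasses = "character",
                    check.names = FALSE, fill = FALSE)
  if (ncol(tab) < 2) stop("dosage table needs an animal-id column plus markers")
  ids <- tab[[1]]
  if (anyDuplicated(ids)) stop("duplicate animal ids in dosage table")
  marker_ids <- colnames(tab)[-1]
  if (anyDuplicated(marker_ids)) stop("duplicate marker ids in dosage table header")
  vals <- as.matrix(tab[, -1, drop = FALSE])
  vals[vals == missingCode] <- NA
  bad <- !is.na(vals) & !(vals %in% c("0", "1", "2"))
  if (any(bad))
    stop("non-dosage token(s) in genotype table: ",
         paste(unique(vals[bad])[1:min(3, sum(bad))], collapse = ", "))
  d <- matrix(as.integer(vals), nrow(vals), ncol(vals),
              dimnames = list(ids, marker_ids))
  map <- if (is.null(mapPath)) {
    data.frame(marker_id = character(), chrom = character(), pos_bp = integer())
  } else {
    m <- read.delim(mapPath, header = TRUE, sep = "\t",
                    colClasses = c("character", "character", "numeric"))
    names(m)[1:3] <- c("marker_id", "chrom", "pos_bp")
    if (anyDuplicated(m$marker_id)) stop("duplicate marker ids in map")
    m[m$marker_id %in% marker_ids, , drop = FALSE]
  }
  GenotypePanel(d, map)
}

#' Write a panel as a dosage table plus marker map
#'
#' Inverse of [readDosageTable()]: round-tripping reproduces the panel.
#'
#' @param panel a [GenotypePanel-class].
#' @param path,mapPath output paths (tab-delimited text).
#' @param missingCode token to write for missing genotypes.
#' @return invisibly, the two paths.
#' @export
writeDosageTable <- function(panel, path, mapPath, missingCode = "NA") {
  stopifnot(is(panel, "GenotypePanel"))
  d <- dosages(panel)
  tab <- data.frame(animal_id = rownames(d), d, check.names = FALSE)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = missingCode)
  write.table(markerMap(panel)[, c("marker_id", "chrom", "pos_bp")], mapPath,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(path, mapPath))
}

#' Read PLINK text-format .ped/.map genotypes
#'
#' Parses the whitespace-delimited PLINK text dialect: six leading .ped
#' columns (family, individual, father, mother, sex, phenotype) then two
#' allele columns per marker, with `"0"` meaning a missing allele. Per
#' marker, the designated A allele is the lexicographically smaller of the
#' observed allele labels (recorded in `metadata$a_allele`); genotypes
#' become dosages of A, and a pair with either allele missing becomes `NA`.
#'
#' @param pedPath,mapPath file paths. The .map file has 4 columns:
#'   chromosome, marker id, genetic position (ignored), bp position.
#' @return a [GenotypePanel-class].
#' @export
readPlinkText <- function(pedPath, mapPath) {
  map <- read.table(mapPath, header = FALSE, colClasses = "character")
  if (ncol(map) < 4) stop(".map needs 4 columns: chrom, id, cM, bp")
  map <- data.frame(marker_id = map[[2]], chrom = map[[1]],
                    pos_bp = as.numeric(map[[4]]))
  ped <- read.table(pedPath, header = FALSE, colClasses = "character")
  m <- nrow(map)
  if (ncol(ped) != 6 + 2 * m)
    stop(sprintf(".ped has %d genotype columns; expected %d (2 per marker, %d markers), or an odd allele-column count",
                 ncol(ped) - 6, 2 * m, m))
  ids <- ped[[2]]
  d <- matrix(NA_integer_, nrow(ped), m, dimnames = list(ids, map$marker_id))
  a_allele <- character(m)
  for (k in seq_len(m)) {
    a1 <- ped[[6 + 2 * k - 1]]
    a2 <- ped[[6 + 2 * k]]
    obs <- setdiff(unique(c(a1, a2)), "0")
    if (length(obs) > 2)
      stop(sprintf("marker %s has %d alleles; only biallelic markers supported",
                   map$marker_id[k], length(obs)))
    A <- if (length(obs)) sort(obs)[1] else NA_character_
    a_allele[k] <- A
    miss <- a1 == "0" | a2 == "0"
    d[, k] <- ifelse(miss, NA_integer_,
                     (a1 == A) + (a2 == A))
  }
  GenotypePanel(d, map, metadata = list(a_allele = setNames(a_allele, map$marker_id)))
}

#' Read dosages from a VCF (optional convenience)
#'
#' Reads biallelic SNP records via the vcfR package, converting the GT field
#' to the dosage of the ALT allele; `./.` becomes missing. Positions and
#' chromosomes come from the VCF itself.
#'
#' @param path VCF path (plain text or bgzipped).
#' @return a [GenotypePanel-class].
#' @export
readVcfGenotypes <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("readVcfGenotypes() needs the vcfR package")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  biallelic <- !grepl(",", fix[, "ALT"]) & nchar(fix[, "REF"]) == 1 &
    nchar(fix[, "ALT"]) == 1
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[biallelic, , drop = FALSE]
  fix <- fix[biallelic, , drop = FALSE]
  ids <- fix[, "ID"]
  ids[is.na(ids) | ids == "."] <- paste0(fix[, "CHROM"], ":", fix[, "POS"])[is.na(ids) | ids == "."]
  dose <- function(g) {
    a <- strsplit(gsub("\\|", "/", g), "/", fixed = FALSE)
    vapply(a, function(x) {
      if (length(x) != 2 || any(x == ".")) NA_integer_ else sum(x == "1")
    }, integer(1))
  }
  d <- apply(gt, 2, dose)
  if (is.null(dim(d))) d <- matrix(d, nrow = 1, dimnames = list(NULL, colnames(gt)))
  d <- t(d)                      # animals x markers
  colnames(d) <- ids
  map <- data.frame(marker_id = ids, chrom = fix[, "CHROM"],
                    pos_bp = as.numeric(fix[, "POS"]))
  GenotypePanel(d, map)
}
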