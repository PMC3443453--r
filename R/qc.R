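#' Marker quality control for a genotype panel
#'
#' Removes markers in five ordered rules, each marker counted once under
#' the first rule that catches it: (i) monomorphic, (ii) unmapped (unknown
#' chromosome or missing position), (iii) on a sex chromosome, (iv) minor
#' allele frequency at or below `mafMin` (strict: MAF = mafMin is removed,
#' MAF > mafMin retained), (v) single-locus HWD chi-square (n f^2) above
#' `hwdChisqMax`. After filtering, dosage columns are optionally re-oriented
#' so the designated A allele is the minor allele (recorded in
#' `metadata$flipped`); downstream signs of disequilibria then refer to the
#' minor alleles consistently and are never re-derived.
#'
#' @param panel a [GenotypePanel-class].
#' @param mafMin MAF removal threshold (default 0.02).
#' @param hwdChisqMax HWD chi-square removal threshold (default 600).
#' @param dropSex remove sex-chromosome markers (default TRUE).
#' @param sexChroms chromosome labels treated as sex chromosomes.
#' @param orientMinor re-orient dosages to count minor-allele copies.
#' @return list with `panel` (filtered [GenotypePanel-class]) and `report`
#'   (a [QCReport-class]).
#' @examples
#' p <- simulateCellProbs(rugCellProbs(c(0.35, 0.15, 0.15, 0.35)),
#'                        n = 200, seed = 1)$panel
#' qcFilter(p)$report
#' @export
qcFilter <- function(panel, mafMin = 0.02, hwdChisqMax = 600,
                     dropSex = TRUE, sexChroms = c("X", "Y", "XY", "MT"),
                     orientMinor = TRUE) {
  stopifnot(is(panel, "GenotypePanel"))
  ls <- locusSummaries(panel)
  n_in <- nrow(ls)
  alive <- rep(TRUE, n_in)
  removed <- integer(0)
  take <- function(cond) {
    hit <- alive & cond
    alive[hit] <<- FALSE
    sum(hit)
  }
  no_calls <- ls$n_called == 0
  removed["monomorphic"] <- take(no_calls | ls$monomorphic %in% TRUE)
  removed["unmapped"] <- take(ls$chrom == "unknown" | is.na(ls$pos_bp))
  removed["sex_chromosome"] <-
    if (dropSex) take(ls$chrom %in% sexChroms) else take(rep(FALSE, n_in))
  removed["maf"] <- take(!is.na(ls$maf) & ls$maf <= mafMin)
  removed["hwd"] <- take(!is.na(ls$hwd_chisq) & ls$hwd_chisq > hwdChisqMax)
  if (!any(alive)) stop("QC removed every marker")
  report <- new("QCReport", nInput = as.integer(n_in), removed = removed,
                nRetained = as.integer(sum(alive)))
  out <- panel[, which(alive)]
  if (orientMinor) {
    pA <- ls$p_A[alive]
    flip <- !is.na(pA) & pA > 0.5
    if (any(flip)) {
      d <- out@dosages
      d[, flip] <- 2L - d[, flip]
      out@dosages <- d
    }
    out@metadata$flipped <- setNames(flip, markerIds(out))
  }
  out@metadata$qc <- as.data.frame(report)
  list(panel = out, report = report)
}
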