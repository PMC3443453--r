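#' Single-locus summary: allele frequency, HWD, fixation index
#'
#' From the unphased genotype counts at one biallelic locus, computes the A
#' allele frequency p_A, minor allele frequency, homozygote frequency P_AA,
#' the Hardy-Weinberg disequilibrium D_A = P_AA - p_A^2, the fixation index
#' f_A = D_A / (p_A p_a), the binomial variance term pi_A = p_A (1 - p_A),
#' and the one-degree-of-freedom HWD chi-square n f_A^2. Missing calls are
#' dropped; `n_called` is the number contributing.
#'
#' @param dosage vector of dosage codes 0/1/2/NA (copies of allele A).
#' @return one-row data.frame with columns `n_called`, `p_A`, `maf`, `P_AA`,
#'   `P_Aa`, `D_A`, `f_A`, `pi_A`, `hwd_chisq`, `monomorphic`. At a
#'   monomorphic locus `f_A` and `hwd_chisq` are `NA` (undefined).
#' @examples
#' locusSummary(c(rep(2, 30), rep(1, 40), rep(0, 30)))  # D_A = 0.05, f_A = 0.2
#' @export
locusSummary <- function(dosage) {
  dosage <- dosage[!is.na(dosage)]
  n <- length(dosage)
  if (n == 0L) stop("all calls missing at locus")
  n2 <- sum(dosage == 2)
  n1 <- sum(dosage == 1)
  .locusFromCounts(n0 = n - n1 - n2, n1 = n1, n2 = n2)
}

.locusFromCounts <- function(n0, n1, n2) {
  n <- n0 + n1 + n2
  p <- (2 * n2 + n1) / (2 * n)
  PAA <- n2 / n
  DA <- PAA - p^2
  pi <- p * (1 - p)
  mono <- p == 0 | p == 1
  f <- ifelse(mono, NA_real_, DA / pi)
  data.frame(n_called = n, p_A = p, maf = pmin(p, 1 - p), P_AA = PAA,
             P_Aa = n1 / n, D_A = DA, f_A = f, pi_A = pi,
             hwd_chisq = ifelse(mono, NA_real_, n * f^2),
             monomorphic = mono)
}

#' Per-marker locus summaries for a whole panel
#'
#' @param panel a [GenotypePanel-class].
#' @return data.frame, one row per marker (in panel order) with `marker_id`,
#'   `chrom`, `pos_bp` and the [locusSummary()] columns. Markers with no
#'   calls at all get `n_called = 0` and `NA` statistics.
#' @export
locusSummaries <- function(panel) {
  stopifnot(is(panel, "GenotypePanel"))
  d <- dosages(panel)
  called <- !is.na(d)
  n2 <- colSums(d == 2, na.rm = TRUE)
  n1 <- colSums(d == 1, na.rm = TRUE)
  n0 <- colSums(called) - n1 - n2
  out <- .locusFromCounts(n0, n1, n2)
  # guard all-missing columns (division by zero above)
  empty <- colSums(called) == 0
  if (any(empty)) out[empty, setdiff(names(out), "n_called")] <- NA
  cbind(markerMap(panel)[, c("marker_id", "chrom", "pos_bp")], out,
        row.names = NULL)
}
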