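## Two-locus engine. Everything operates on flattened 3x3 cell tables in the
## column order .CELL_NAMES (g00, g01, ..., g22; first digit = A dosage,
## second = B dosage). The same code serves three callers:
##   * data mode: observed cell proportions with finite n (plug-in / saturated
##     ML estimation -- the estimators ARE the parameter formulas applied to
##     observed proportions);
##   * population mode: exact cell probabilities with n = Inf, so generator
##     truths come from the identical formulas (plug-in identity);
##   * the genome scan, which passes thousands of rows at once.

#' Cross-tabulate the nine unphased two-locus genotype classes
#'
#' Counts animals by (dosage at marker i, dosage at marker j) over animals
#' with both markers called (pairwise-complete). The two double-heterozygote
#' phases are indistinguishable in unphased data and fall together in the
#' (1,1) cell.
#'
#' @param panel a [GenotypePanel-class].
#' @param i,j marker ids or column indices, `i != j`.
#' @return 3x3 integer matrix, rows = A dosage 0:2, cols = B dosage 0:2,
#'   with `attr(,"n")` the number of pairwise-complete animals.
#' @examples
#' p <- simulateCellProbs(w1 <- c(0.5, rep(0, 7), 0.5), n = 100, seed = 1)
#' twoLocusCounts(p$panel, 1, 2)
#' @export
twoLocusCounts <- function(panel, i, j) {
  stopifnot(is(panel, "GenotypePanel"))
  d <- dosages(panel)
  if (is.character(i)) i <- match(i, colnames(d))
  if (is.character(j)) j <- match(j, colnames(d))
  if (any(is.na(c(i, j))) || i == j) stop("need two distinct markers present in the panel")
  x <- d[, i]; y <- d[, j]
  keep <- !is.na(x) & !is.na(y)
  if (!any(keep)) stop("no animal has both markers called")
  tab <- table(factor(x[keep], levels = 0:2), factor(y[keep], levels = 0:2))
  out <- matrix(as.integer(tab), 3, 3, dimnames = list(A = 0:2, B = 0:2))
  attr(out, "n") <- sum(out)
  out
}

## Coerce a 3x3 table (counts or probabilities) to a 1x9 proportion row + n.
.asCellRow <- function(x, n = NULL) {
  if (is.matrix(x)) {
    stopifnot(dim(x) == c(3, 3))
    v <- as.numeric(t(x))         # row-major: x slow, y fast = .CELL_* order
  } else {
    stopifnot(length(x) == 9)
    v <- as.numeric(x)
  }
  if (any(v < 0)) stop("negative cell values")
  tot <- sum(v)
  if (tot <= 0) stop("empty cell table")
  if (is.null(n)) {
    n <- if (isTRUE(all.equal(tot, 1, tolerance = 1e-6))) Inf else sum(v)
  }
  list(Q = matrix(v / tot, 1, 9, dimnames = list(NULL, .CELL_NAMES)), n = n)
}

## Vectorized moments/disequilibria from P x 9 cell-proportion rows.
## Returns a data.frame of P rows. All formulas are exact algebra on the
## proportions; no distributional assumption enters here.
.diseqStats <- function(Q, zygotic = c("designated", "opposite")) {
  zygotic <- match.arg(zygotic)
  wx <- .CELL_X / 2; wy <- .CELL_Y / 2
  pA <- drop(Q %*% wx)
  pB <- drop(Q %*% wy)
  PAA <- drop(Q %*% as.numeric(.CELL_X == 2))
  PBB <- drop(Q %*% as.numeric(.CELL_Y == 2))
  DA <- PAA - pA^2
  DB <- PBB - pB^2
  piA <- pA * (1 - pA)
  piB <- pB * (1 - pB)
  delta <- drop(Q %*% (.CELL_X * .CELL_Y / 2)) - 2 * pA * pB
  PAAB <- drop(Q %*% ((.CELL_X == 2) * .CELL_Y / 2))
  PABB <- drop(Q %*% (.CELL_X * (.CELL_Y == 2) / 2))
  dAAB <- PAAB - pA^2 * pB - pB * DA - pA * delta
  dABB <- PABB - pA * pB^2 - pA * DB - pB * delta
  PAABB <- Q[, 9L]
  dAABB <- PAABB - PAA * PBB - 2 * pA * dABB - 2 * pB * dAAB -
    2 * pA * pB * delta - delta^2
  if (zygotic == "designated") {
    omega <- PAABB - PAA * PBB
    zAA <- PAA; zBB <- PBB
  } else {
    # zygotic LD of the opposite (aa/bb) double homozygote: the g00 corner
    zAA <- drop(Q %*% as.numeric(.CELL_X == 0))
    zBB <- drop(Q %*% as.numeric(.CELL_Y == 0))
    omega <- Q[, 1L] - zAA * zBB
  }
  monoA <- piA <= 0
  monoB <- piB <= 0
  mono <- monoA | monoB
  # composite-LD squared correlation; denominator is the no-higher-order
  # approximation (pi + D) at each locus
  denC <- (piA + DA) * (piB + DB)
  r2cld <- ifelse(mono | denC <= 0, NA_real_, delta^2 / denC)
  denZ <- zAA * (1 - zAA) * zBB * (1 - zBB)
  r2zld <- ifelse(denZ <= 0, NA_real_, omega^2 / denZ)
  out <- data.frame(p_A = pA, p_B = pB, maf_A = pmin(pA, 1 - pA),
                    maf_B = pmin(pB, 1 - pB),
                    P_AA = PAA, P_BB = PBB, D_A = DA, D_B = DB,
                    pi_A = piA, pi_B = piB,
                    delta_AB = delta, d_AAB = dAAB, d_ABB = dABB,
                    delta_AABB = dAABB, omega_AABB = omega,
                    r2_cld = r2cld, r2_zld = r2zld,
                    monomorphic = mono)
  if (any(mono)) {
    und <- c("delta_AB", "d_AAB", "d_ABB", "delta_AABB", "r2_cld")
    out[mono, und] <- NA_real_
  }
  out
}

#' EM estimation of gametic LD from unphased two-locus genotypes
#'
#' Estimates the four haplotype frequencies by the standard two-locus EM
#' algorithm in which only the double-heterozygote cell is phase-ambiguous
#' (its coupling/repulsion split is re-weighted by the current haplotype
#' frequencies, i.e. assuming random union of gametes within that cell).
#' The gametic LD is D_AB = P_AB - p_A p_B and its squared correlation is
#' r2 = D^2 / (p_A p_a p_B p_b).
#'
#' @param counts 3x3 genotype count table (e.g. from [twoLocusCounts()]), or
#'   a table of exact cell probabilities (then the EM runs on expected
#'   fractions — population mode).
#' @param tol convergence tolerance on the max absolute change in haplotype
#'   frequency per iteration.
#' @param maxIter iteration cap; non-convergence is flagged, the last
#'   iterate returned.
#' @return list with `haplotypes` (named AB, Ab, aB, ab), `D` (gametic LD),
#'   `r2` , `converged`, `flat` (TRUE when the likelihood is flat at the
#'   linkage-equilibrium start, e.g. an all-double-heterozygote table, so D
#'   = 0 is reported by convention rather than an arbitrary phase choice),
#'   and `iterations`.
#' @examples
#' w1 <- matrix(0, 3, 3); w1[1, 1] <- 50; w1[3, 3] <- 50
#' emGameticLD(w1)$D   # 0.25: phase is unambiguous without double hets
#' @export
emGameticLD <- function(counts, tol = 1e-10, maxIter = 1000L) {
  row <- .asCellRow(counts)
  em <- .emGametic(row$Q, tol = tol, maxIter = maxIter)
  list(haplotypes = c(AB = em$hAB, Ab = em$hAb, aB = em$haB, ab = em$hab),
       D = em$d_gametic, r2 = em$r2_gld, converged = em$em_converged,
       flat = em$em_flat, iterations = em$em_iter)
}

## Vectorized EM over P rows of cell proportions.
.emGametic <- function(Q, tol = 1e-10, maxIter = 1000L) {
  pA <- drop(Q %*% (.CELL_X / 2))
  pB <- drop(Q %*% (.CELL_Y / 2))
  ## fixed (phase-known) gamete contributions, per copy out of 2 per animal
  q11 <- Q[, .CELL_NAMES == "g11"]
  fAB <- (2 * Q[, 9L] + Q[, .CELL_NAMES == "g21"] + Q[, .CELL_NAMES == "g12"]) / 2
  fAb <- (2 * Q[, .CELL_NAMES == "g20"] + Q[, .CELL_NAMES == "g21"] +
            Q[, .CELL_NAMES == "g10"]) / 2
  faB <- (2 * Q[, .CELL_NAMES == "g02"] + Q[, .CELL_NAMES == "g01"] +
            Q[, .CELL_NAMES == "g12"]) / 2
  fab <- (2 * Q[, 1L] + Q[, .CELL_NAMES == "g01"] + Q[, .CELL_NAMES == "g10"]) / 2
  ## init at linkage equilibrium
  hAB <- pA * pB; hAb <- pA * (1 - pB); haB <- (1 - pA) * pB
  hab <- (1 - pA) * (1 - pB)
  iter <- 0L
  active <- rep(TRUE, nrow(Q))
  delta1 <- rep(NA_real_, nrow(Q))
  repeat {
    iter <- iter + 1L
    den <- hAB * hab + hAb * haB
    pc <- ifelse(den > 0, hAB * hab / den, 0.5)  # coupling weight
    nAB <- fAB + q11 * pc / 2
    nab <- fab + q11 * pc / 2
    nAb <- fAb + q11 * (1 - pc) / 2
    naB <- faB + q11 * (1 - pc) / 2
    ch <- pmax(abs(nAB - hAB), abs(nAb - hAb), abs(naB - haB), abs(nab - hab))
    hAB <- nAB; hAb <- nAb; haB <- naB; hab <- nab
    if (iter == 1L) delta1 <- ch
    active <- ch >= tol
    if (!any(active) || iter >= maxIter) break
  }
  data.frame(hAB = hAB, hAb = hAb, haB = haB, hab = hab,
             d_gametic = hAB - pA * pB,
             r2_gld = ifelse(pA %in% c(0, 1) | pB %in% c(0, 1), NA_real_,
                             (hAB - pA * pB)^2 /
                               (pA * (1 - pA) * pB * (1 - pB))),
             em_converged = !active, em_flat = q11 > 0 & delta1 < tol,
             em_iter = iter)
}
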