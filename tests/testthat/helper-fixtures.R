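# Shared fixtures and independent oracles.

# W1: 50 animals AABB + 50 animals aabb (perfect coupling, no heterozygotes).
w1Counts <- function() {
  m <- matrix(0, 3, 3, dimnames = list(A = 0:2, B = 0:2))
  m[1, 1] <- 50; m[3, 3] <- 50
  m
}

w1Panel <- function() {
  d <- rbind(matrix(2L, 50, 2), matrix(0L, 50, 2))
  dimnames(d) <- list(paste0("an", 1:100), c("mA", "mB"))
  GenotypePanel(d, data.frame(marker_id = c("mA", "mB"), chrom = c("1", "2"),
                              pos_bp = c(1, 1)))
}

# independence: product of HWE margins at pA = pB = 0.5
hweIndepProbs <- function(pA = 0.5, pB = 0.5) {
  as.numeric(t(outer(dbinom(0:2, 2, pA), dbinom(0:2, 2, pB))))
}

randomCellTable <- function(n = 300) {
  q <- runif(9)
  matrix(rmultinom(1, n, q / sum(q)), 3, 3, byrow = TRUE)
}

# Brute-force oracle: cross-tabulate a panel's marker pair with an explicit
# loop over animals (independent of the package's indicator-matrix path).
bruteCounts <- function(panel, i, j) {
  d <- dosages(panel)
  out <- matrix(0L, 3, 3)
  for (a in seq_len(nrow(d))) {
    x <- d[a, i]; y <- d[a, j]
    if (!is.na(x) && !is.na(y)) out[x + 1, y + 1] <- out[x + 1, y + 1] + 1L
  }
  out
}

# Brute-force oracle for mixture-population disequilibria: builds the exact
# nine-cell table by direct summation over breeds and genotype classes, then
# derives each disequilibrium from raw frequency moments (definitions only,
# no shared code with the estimators).
bruteMixtureDiseq <- function(freqs, weights) {
  q <- matrix(0, 3, 3)
  for (k in seq_along(weights)) {
    q <- q + weights[k] * outer(dbinom(0:2, 2, freqs[k, 1]),
                                dbinom(0:2, 2, freqs[k, 2]))
  }
  x <- matrix(0:2, 3, 3); y <- t(x)
  pA <- sum(x / 2 * q); pB <- sum(y / 2 * q)
  PAA <- sum(q[3, ]); PBB <- sum(q[, 3])
  DA <- PAA - pA^2; DB <- PBB - pB^2
  delta <- sum(x * y / 2 * q) - 2 * pA * pB
  PAAB <- sum((x == 2) * y / 2 * q)
  PABB <- sum(x * (y == 2) / 2 * q)
  dAAB <- PAAB - pA^2 * pB - pB * DA - pA * delta
  dABB <- PABB - pA * pB^2 - pA * DB - pB * delta
  dAABB <- q[3, 3] - PAA * PBB - 2 * pA * dABB - 2 * pB * dAAB -
    2 * pA * pB * delta - delta^2
  list(p_A = pA, D_A = DA, delta_AB = delta, d_AAB = dAAB, d_ABB = dABB,
       delta_AABB = dAABB, omega = q[3, 3] - PAA * PBB)
}
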