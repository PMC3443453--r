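#' Haplotype frequencies from allele frequencies and gametic LD
#'
#' @param pA,pB allele frequencies of A and B.
#' @param D gametic LD, constrained so all four frequencies are in [0, 1].
#' @return named vector (AB, Ab, aB, ab).
#' @export
haplotypeFreqs <- function(pA, pB, D = 0) {
  h <- c(AB = pA * pB + D, Ab = pA * (1 - pB) - D,
         aB = (1 - pA) * pB - D, ab = (1 - pA) * (1 - pB) + D)
  if (any(h < -1e-12) || abs(sum(h) - 1) > 1e-12)
    stop("inadmissible (pA, pB, D) combination")
  pmax(h, 0)
}

#' Exact unphased genotype cell probabilities under random union of gametes
#'
#' Pairs two i.i.d. gametes from the given haplotype distribution; the
#' resulting nine-cell table has all non-gametic, trigenic and quadrigenic
#' disequilibria equal to zero and composite LD equal to the gametic LD.
#'
#' @param hap haplotype frequencies (AB, Ab, aB, ab), summing to 1.
#' @return length-9 cell probability vector in cell order g00 ... g22.
#' @examples
#' pairDiseq(rugCellProbs(haplotypeFreqs(0.5, 0.5, 0.1)))$omega_AABB # 0.06
#' @export
rugCellProbs <- function(hap) {
  stopifnot(length(hap) == 4)
  if (any(hap < 0) || abs(sum(hap) - 1) > 1e-12)
    stop("hap must be a probability vector of length 4")
  ga <- c(1, 1, 0, 0)  # A-dosage carried by each gamete class
  gb <- c(1, 0, 1, 0)
  cells <- setNames(numeric(9), .CELL_NAMES)
  for (u in 1:4) for (v in 1:4) {
    x <- ga[u] + ga[v]; y <- gb[u] + gb[v]
    k <- paste0("g", x, y)
    cells[k] <- cells[k] + hap[u] * hap[v]
  }
  cells
}

#' Exact cell probabilities for a mixture of random-mating subpopulations
#'
#' Generation-0 admixture (Wahlund structure): an individual belongs to
#' breed k with probability `weights[k]` and its genotype at each locus is
#' Hardy-Weinberg within breed, with linkage equilibrium within breed.
#' Differences in breed allele frequencies induce HWD at each locus and
#' digenic through quadrigenic disequilibria between loci, even for
#' unlinked markers.
#'
#' @param breedFreqs K x 2 matrix: allele-A/allele-B frequency per breed.
#' @param weights mixing proportions, summing to 1.
#' @return length-9 cell probability vector.
#' @examples
#' # two breeds at p = 0.9 / 0.1, 70:30 -> trigenic D_AAB = -0.043008
#' pairDiseq(mixtureCellProbs(rbind(c(0.9, 0.9), c(0.1, 0.1)),
#'                            c(0.7, 0.3)))$d_AAB
#' @export
mixtureCellProbs <- function(breedFreqs, weights) {
  breedFreqs <- as.matrix(breedFreqs)
  stopifnot(ncol(breedFreqs) == 2, length(weights) == nrow(breedFreqs))
  if (abs(sum(weights) - 1) > 1e-12) stop("weights must sum to 1")
  cells <- setNames(numeric(9), .CELL_NAMES)
  for (k in seq_along(weights)) {
    da <- stats::dbinom(0:2, 2, breedFreqs[k, 1])
    db <- stats::dbinom(0:2, 2, breedFreqs[k, 2])
    # t(outer(da, db)) flattens with the B dosage fastest, matching .CELL_NAMES
    cells <- cells + weights[k] * as.numeric(t(outer(da, db)))
  }
  cells
}

#' Exact cell probabilities for an admixed population after random mating
#'
#' Generation 0 is the Wahlund mixture of [mixtureCellProbs()]. Each later
#' generation forms zygotes by random union of gametes drawn from random
#' parents, with recombination fraction `c` between the two loci. Within-
#' breed linkage equilibrium makes the gamete-pool LD after the first round
#' of meiosis equal to the mixture LD D0 = sum_k w_k p_kA p_kB - pA pB,
#' which then decays by (1 - c) per additional generation; from generation
#' 1 on the population is a random union of such gametes.
#'
#' @inheritParams mixtureCellProbs
#' @param generations number of random-mating generations (0 = raw mixture).
#' @param c recombination fraction between the loci (0.5 = unlinked).
#' @return length-9 cell probability vector.
#' @export
admixtureCellProbs <- function(breedFreqs, weights, generations = 0, c = 0.5) {
  if (generations == 0) return(mixtureCellProbs(breedFreqs, weights))
  breedFreqs <- as.matrix(breedFreqs)
  pA <- sum(weights * breedFreqs[, 1])
  pB <- sum(weights * breedFreqs[, 2])
  D0 <- sum(weights * breedFreqs[, 1] * breedFreqs[, 2]) - pA * pB
  D <- D0 * (1 - c)^(generations - 1)
  rugCellProbs(haplotypeFreqs(pA, pB, D))
}

#' Exact population disequilibria for a two-locus genotype distribution
#'
#' Applies the package's estimators to exact cell probabilities (the
#' n -> infinity plug-in identity), so generator truths are defined by the
#' very same formulas that are applied to data.
#'
#' @param cellProbs length-9 probability vector or 3x3 probability matrix.
#' @return one-row data.frame of population values (sampling columns NA).
#' @export
populationTruth <- function(cellProbs) {
  pairDiseq(cellProbs, n = Inf)
}

.pairPanel <- function(x, y, seedInfo = list()) {
  d <- cbind(mA = as.integer(x), mB = as.integer(y))
  rownames(d) <- paste0("an", seq_len(nrow(d)))
  map <- data.frame(marker_id = c("mA", "mB"), chrom = c("1", "2"),
                    pos_bp = c(1, 1))
  GenotypePanel(d, map, metadata = seedInfo)
}

#' Simulate one marker pair under random union of gametes
#'
#' Draws 2n gametes i.i.d. from the haplotype distribution and pairs them
#' at random into n zygotes. The companion truth has all non-gametic and
#' higher-order disequilibria exactly zero.
#'
#' @param hap haplotype frequencies (AB, Ab, aB, ab).
#' @param n number of diploid animals.
#' @param seed RNG seed.
#' @return list with `panel` (a two-marker [GenotypePanel-class], markers
#'   on different chromosomes) and `truth` ([populationTruth()] row).
#' @export
simulateRUG <- function(hap, n, seed = NULL) {
  if (any(hap < 0) || abs(sum(hap) - 1) > 1e-12)
    stop("hap must be a probability vector of length 4")
  if (!is.null(seed)) set.seed(seed)
  g <- sample.int(4L, 2L * n, replace = TRUE, prob = hap)
  ga <- c(1L, 1L, 0L, 0L)[g]
  gb <- c(1L, 0L, 1L, 0L)[g]
  x <- ga[1:n] + ga[(n + 1):(2 * n)]
  y <- gb[1:n] + gb[(n + 1):(2 * n)]
  list(panel = .pairPanel(x, y, list(sim = list(mode = "rug", hap = hap,
                                                n = n, seed = seed))),
       truth = populationTruth(rugCellProbs(hap)))
}

#' Simulate one marker pair from a saturated nine-cell distribution
#'
#' Multinomial sampling of n diploids from arbitrary unphased two-locus
#' genotype probabilities — the saturated model used to exercise every
#' estimator against known truth.
#'
#' @param cellProbs length-9 probability vector (cell order g00 ... g22) or
#'   3x3 probability matrix.
#' @param n number of animals.
#' @param seed RNG seed.
#' @return list with `panel` and `truth` as in [simulateRUG()].
#' @export
simulateCellProbs <- function(cellProbs, n, seed = NULL) {
  q <- drop(.asCellRow(cellProbs)$Q)
  if (!is.null(seed)) set.seed(seed)
  counts <- drop(rmultinom(1, n, q))
  cls <- rep.int(seq_len(9L), counts)
  cls <- cls[sample.int(length(cls))]
  list(panel = .pairPanel(.CELL_X[cls], .CELL_Y[cls],
                          list(sim = list(mode = "cell_probs", probs = q,
                                          n = n, seed = seed))),
       truth = populationTruth(q))
}

## recombination fraction between adjacent sorted markers of a map
.adjacentRecomb <- function(map, rate = 1e-8) {
  m <- nrow(map)
  if (m < 2) return(numeric(0))
  same <- map$chrom[-1] == map$chrom[-m]
  d <- map$pos_bp[-1] - map$pos_bp[-m]
  ifelse(same, pmin(0.5, d * rate), 0.5)
}

## effective recombination fraction between markers i < j (map order):
## probability of an odd number of crossovers over the intervening intervals
.pairRecomb <- function(cAdj, i, j) {
  if (i > j) { t <- i; i <- j; j <- t }
  (1 - prod(1 - 2 * cAdj[i:(j - 1)])) / 2
}

#' Simulate an admixed (multi-breed composite) population
#'
#' Generation 0 samples each animal's breed from `weights` and both of its
#' haplotypes from that breed's allele frequencies (Hardy-Weinberg and
#' linkage equilibrium within breed — the Wahlund regime with
#' admixture-induced HWD and LD at all distances). Each later generation is
#' produced by random union of gametes from random parents, recombining
#' between adjacent markers at fraction min(0.5, distance_bp x 1e-8)
#' (1 cM = 1 Mb) within a chromosome and 0.5 across chromosomes.
#'
#' @param breedFreqs K x m matrix of per-breed allele-A frequencies.
#' @param weights breed mixing proportions (sum to 1).
#' @param generations random-mating generations after the initial cross.
#' @param n number of animals.
#' @param map optional marker map (`marker_id`, `chrom`, `pos_bp`); default
#'   places all markers on distinct chromosomes (free recombination).
#' @param seed RNG seed.
#' @param truth compute exact population truths for all marker pairs
#'   (quadratic in m; default only when m <= 40).
#' @return list with `panel` and, when requested, `truth`: one row per
#'   marker pair of exact population disequilibria from
#'   [admixtureCellProbs()].
#' @export
simulateAdmixture <- function(breedFreqs, weights, generations = 0, n,
                              map = NULL, seed = NULL,
                              truth = ncol(breedFreqs) <= 40) {
  breedFreqs <- as.matrix(breedFreqs)
  K <- nrow(breedFreqs); m <- ncol(breedFreqs)
  if (length(weights) != K || abs(sum(weights) - 1) > 1e-12)
    stop("weights must match breedFreqs rows and sum to 1")
  if (is.null(map))
    map <- data.frame(marker_id = paste0("m", seq_len(m)),
                      chrom = as.character(seq_len(m)), pos_bp = 1)
  if (is.null(colnames(breedFreqs))) colnames(breedFreqs) <- map$marker_id
  ord <- order(map$chrom, map$pos_bp, map$marker_id)
  map <- map[ord, , drop = FALSE]
  breedFreqs <- breedFreqs[, ord, drop = FALSE]
  if (!is.null(seed)) set.seed(seed)
  breed <- sample.int(K, n, replace = TRUE, prob = weights)
  pk <- breedFreqs[breed, , drop = FALSE]
  H1 <- matrix(rbinom(n * m, 1L, pk), n, m)
  H2 <- matrix(rbinom(n * m, 1L, pk), n, m)
  if (generations > 0) {
    cAdj <- .adjacentRecomb(map)
    gamete <- function(H1, H2, parents) {
      S <- matrix(runif(length(parents) * (m - 1)) <
                    rep(cAdj, each = length(parents)),
                  length(parents), m - 1)
      start <- runif(length(parents)) < 0.5
      parity <- (start + t(apply(cbind(0, S), 1, cumsum))) %% 2
      ifelse(parity == 0, H1[parents, , drop = FALSE],
             H2[parents, , drop = FALSE])
    }
    for (g in seq_len(generations)) {
      p1 <- sample.int(n, n, replace = TRUE)
      p2 <- sample.int(n, n, replace = TRUE)
      N1 <- gamete(H1, H2, p1)
      N2 <- gamete(H1, H2, p2)
      H1 <- N1; H2 <- N2
    }
  }
  d <- H1 + H2
  dimnames(d) <- list(paste0("an", seq_len(n)), map$marker_id)
  panel <- GenotypePanel(d, map,
                         metadata = list(sim = list(mode = "admixture",
                                                    weights = weights,
                                                    generations = generations,
                                                    n = n, seed = seed)))
  out <- list(panel = panel)
  if (isTRUE(truth) && m >= 2) {
    cAdj <- .adjacentRecomb(map)
    rows <- list()
    for (i in seq_len(m - 1)) for (j in seq((i + 1), m)) {
      cc <- .pairRecomb(cAdj, i, j)
      tr <- populationTruth(admixtureCellProbs(breedFreqs[, c(i, j)], weights,
                                               generations, cc))
      rows[[length(rows) + 1L]] <-
        cbind(data.frame(marker_i = map$marker_id[i],
                         marker_j = map$marker_id[j], recomb = cc), tr)
    }
    out$truth <- do.call(rbind, rows)
  }
  out
}

## Approximate bovine autosome lengths (Mb) used as default genome shape.
.BOVINE_MB <- c(158, 137, 121, 120, 120, 119, 113, 113, 105, 104, 107, 91,
                84, 84, 85, 81, 75, 66, 64, 72, 71, 61, 52, 62, 42, 52, 45,
                46, 51)

#' Simulate a genome-wide panel with distance-decaying LD
#'
#' An end-to-end fixture for the genome scan, emulating a multi-breed
#' composite population: marker positions are placed uniformly at random
#' on each chromosome; per-breed allele frequencies deviate from a common
#' base frequency by a latent field that is autocorrelated along the
#' chromosome over several scales (a mixture of exponential correlation
#' scales 0.02, 0.1, 0.5 and 2.5 x `decayScaleBp`, giving the slower-than-
#' exponential LD decay seen in real panels); animals are then sampled from
#' the Wahlund mixture (optionally followed by random-mating generations
#' with 1 cM = 1 Mb recombination). Breed differentiation that is
#' correlated between nearby markers yields composite/gametic LD decaying
#' with physical distance, admixture-induced HWD, and nonzero trigenic and
#' quadrigenic disequilibria, with a long-range LD floor between distant
#' and non-syntenic markers — the qualitative structure of a composite
#' population.
#'
#' @param chromLengthsBp chromosome lengths in bp (default: 29 bovine-like
#'   autosomes).
#' @param markersPerChrom markers per chromosome (recycled).
#' @param n number of animals (default 1023).
#' @param decayScaleBp overall LD-decay scale in bp (default 1 Mb); the
#'   five correlation scales of the latent differentiation field are
#'   0.02, 0.1, 0.5, 2.5 and 12.5 times this value.
#' @param scaleWeights variance share of each correlation scale.
#' @param nBreeds,weights founder lines and their mixing proportions
#'   (default 12 lines with gently unequal weights).
#' @param logitSd standard deviation of breed deviations on the logit
#'   scale (differentiation strength; default 1.2).
#' @param baseFreqRange range of the base A-allele frequency (minor-allele
#'   oriented; default 0.1-0.5).
#' @param generations random-mating generations after the founder mixture.
#' @param seed RNG seed.
#' @return list with `panel` (a [GenotypePanel-class]), `breedFreqs` (the
#'   exact per-breed allele frequencies, for truth computations via
#'   [admixtureCellProbs()]) and `weights`.
#' @export
simulateGenome <- function(chromLengthsBp = .BOVINE_MB * 1e6,
                           markersPerChrom = 50L, n = 1023L,
                           decayScaleBp = 1e6,
                           scaleWeights = c(0.15, 0.15, 0.2, 0.3, 0.2),
                           nBreeds = 12L, weights = NULL, logitSd = 1.2,
                           baseFreqRange = c(0.1, 0.5),
                           generations = 0L, seed = NULL) {
  stopifnot(all(chromLengthsBp > 0), all(markersPerChrom > 1))
  if (is.null(weights)) {
    weights <- seq(1.3, 0.7, length.out = nBreeds)
    weights <- weights / sum(weights)
  }
  if (!is.null(seed)) set.seed(seed)
  markersPerChrom <- rep_len(markersPerChrom, length(chromLengthsBp))
  scales <- decayScaleBp * c(0.02, 0.1, 0.5, 2.5, 12.5)
  stopifnot(length(scaleWeights) == length(scales))
  scaleWeights <- scaleWeights / sum(scaleWeights)
  maps <- list(); freqs <- list()
  for (ch in seq_along(chromLengthsBp)) {
    m <- markersPerChrom[ch]
    pos <- sort(sample.int(chromLengthsBp[ch], m))
    base <- runif(m, baseFreqRange[1], baseFreqRange[2])
    dgap <- diff(pos)
    Z <- matrix(0, nBreeds, m)
    for (si in seq_along(scales)) {
      a <- exp(-dgap / scales[si])
      Zs <- matrix(0, nBreeds, m)
      Zs[, 1] <- stats::rnorm(nBreeds)
      for (k in seq_len(m - 1))
        Zs[, k + 1] <- a[k] * Zs[, k] + sqrt(1 - a[k]^2) * stats::rnorm(nBreeds)
      Z <- Z + sqrt(scaleWeights[si]) * Zs
    }
    pk <- stats::plogis(stats::qlogis(base)[col(Z)] + logitSd * Z)
    colnames(pk) <- paste0("c", ch, "m", seq_len(m))
    maps[[ch]] <- data.frame(marker_id = colnames(pk),
                             chrom = as.character(ch), pos_bp = pos)
    freqs[[ch]] <- pk
  }
  map <- do.call(rbind, maps)
  breedFreqs <- do.call(cbind, freqs)
  sim <- simulateAdmixture(breedFreqs, weights, generations = generations,
                           n = n, map = map, truth = FALSE)
  sim$panel@metadata$sim <- list(mode = "genome", n = n, seed = seed,
                                 decayScaleBp = decayScaleBp,
                                 weights = weights, logitSd = logitSd,
                                 generations = generations)
  list(panel = sim$panel, breedFreqs = breedFreqs, weights = weights)
}
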