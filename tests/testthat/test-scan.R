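toyPanel <- function(n = 60, m = 10, seed = 91, miss = 0.03) {
  set.seed(seed)
  p <- runif(m, 0.15, 0.5)
  d <- matrix(rbinom(n * m, 2, rep(p, each = n)), n, m,
              dimnames = list(paste0("an", 1:n), paste0("m", 1:m)))
  d[runif(n * m) < miss] <- NA
  map <- data.frame(marker_id = paste0("m", 1:m),
                    chrom = rep(c("1", "2"), length.out = m),
                    pos_bp = rep(seq(1e6, 5e6, length.out = m / 2), 2))
  GenotypePanel(d, map)
}

test_that("pair enumeration covers the right combinatorics", {
  map1 <- data.frame(marker_id = c("a", "b", "c"), chrom = "1",
                     pos_bp = c(1e6, 4e6, 9e6))
  syn <- enumeratePairs(map1, "syntenic")
  expect_identical(nrow(syn), 3L)
  expect_error(enumeratePairs(map1, "nonsyntenic"))
  expect_equal(sort(syn$distance_bp), c(3e6, 5e6, 8e6))

  map2 <- data.frame(marker_id = letters[1:4], chrom = c("1", "1", "2", "2"),
                     pos_bp = c(1, 2, 1, 2))
  both <- enumeratePairs(map2, "both")
  expect_identical(sum(both$syntenic), 2L)
  expect_identical(sum(!both$syntenic), 4L)  # 2 x 2 cross-chromosome

  # unmapped markers never enter pairs
  map3 <- rbind(map2, data.frame(marker_id = "zz", chrom = "unknown",
                                 pos_bp = NA))
  expect_false("zz" %in% unlist(enumeratePairs(map3, "both")[, c("marker_i", "marker_j")]))

  # seeded subsampling is reproducible and records the enumerated total
  mapw <- data.frame(marker_id = paste0("m", 1:30), chrom = "1",
                     pos_bp = 1:30 * 1e5)
  s1 <- enumeratePairs(mapw, "syntenic", subsample = 50, seed = 4)
  s2 <- enumeratePairs(mapw, "syntenic", subsample = 50, seed = 4)
  expect_identical(s1, s2)
  expect_identical(attr(s1, "n_enumerated"), 435L)
  expect_identical(nrow(s1), 50L)
})

test_that("the scan is schema-complete, deterministic and matches per-pair calls", {
  panel <- toyPanel()
  rows <- scanPairs(panel, mode = "both", minN = 2)
  expect_identical(nrow(rows), 45L)         # choose(10, 2)
  expect_true(all(c("delta_AB", "d_AAB", "d_ABB", "delta_AABB", "omega_AABB",
                    "d_gametic", "x2_cld", "phi2_zld", "n", "distance_bp",
                    "syntenic") %in% names(rows)))
  rows2 <- scanPairs(panel, mode = "both", minN = 2)
  expect_identical(rows, rows2)

  # oracle: every row equals the single-pair path on the same markers
  idx <- c(1, 10, 27, 45)
  for (r in idx) {
    tab <- twoLocusCounts(panel, rows$marker_i[r], rows$marker_j[r])
    one <- pairDiseq(tab)
    expect_equal(rows$delta_AB[r], one$delta_AB, tolerance = 1e-12)
    expect_equal(rows$delta_AABB[r], one$delta_AABB, tolerance = 1e-12)
    expect_equal(rows$x2_cld[r], one$x2_cld, tolerance = 1e-12)
    expect_equal(rows$x2_d_AAB[r], one$x2_d_AAB, tolerance = 1e-10)
    expect_equal(rows$d_gametic[r], one$d_gametic, tolerance = 1e-7)
    expect_identical(rows$n[r], sum(tab))
  }
})

test_that("distance binning uses half-open intervals and exact tallies", {
  panel <- toyPanel()
  rows <- scanPairs(panel, minN = 2)
  b <- binByDistance(rows)
  # every syntenic pair lands in exactly one bin
  expect_identical(sum(b$n_pairs[b$component == "cld"]),
                   sum(rows$syntenic & !is.na(rows$phi2_cld)))

  fake <- rows[1:2, ]
  fake$distance_bp <- c(10e3, 30e3)
  fake$phi2_cld <- c(0.3, 0.2); fake$x2_cld <- c(20, 10)
  fb <- binByDistance(fake, components = "cld")
  expect_identical(fb$n_pairs[fb$bin == "[0,0.025)"], 1L)
  expect_identical(fb$n_pairs[fb$bin == "[0.025,0.05)"], 1L)
  # threshold fraction: {0.3, 0.2} vs 0.25 -> one half
  fake2 <- fake; fake2$distance_bp <- c(10e3, 12e3)
  fb2 <- binByDistance(fake2, components = "cld")
  expect_equal(fb2$frac_ge_threshold[fb2$bin == "[0,0.025)"], 0.5)
  # empty bins report zero pairs and undefined statistics, not NaN poison
  expect_identical(fb$n_pairs[fb$bin == "[3,5)"], 0L)
  expect_true(is.na(fb$mean_phi2[fb$bin == "[3,5)"]))
})

test_that("linked/unlinked split respects the 50 Mb boundary exactly", {
  rows <- scanPairs(toyPanel(), minN = 2)
  rows <- rows[1:4, ]
  rows$chrom_i <- "1"; rows$syntenic <- TRUE
  rows$distance_bp <- c(5e7, 5e7 + 1, 1e6, 6e7)
  rows[paste0("x2_", c("gld", "cld", "zld", "d_AAB", "d_ABB", "delta_AABB"))] <- 1
  rows[paste0("phi2_", c("gld", "cld", "zld", "d_AAB", "d_ABB", "delta_AABB"))] <- 0.01
  s <- linkedUnlinkedSummary(rows, components = "cld")
  expect_identical(s$n_pairs[s$group == "linked"], 2L)   # <= 50 Mb inclusive
  expect_identical(s$n_pairs[s$group == "unlinked"], 2L)
  expect_equal(s$power, c(0, 0))                         # X2 = 1 < 3.84

  # a short chromosome reports no unlinked cell
  short <- rows; short$distance_bp <- c(1e6, 2e6, 3e6, 4e6)
  s2 <- linkedUnlinkedSummary(short, components = "cld")
  expect_true(is.na(s2$power[s2$group == "unlinked"]))
  expect_identical(s2$n_pairs[s2$group == "unlinked"], 0L)
})

test_that("MAF classes are half-open with a closed top and split by synteny", {
  rows <- scanPairs(toyPanel(), mode = "both", minN = 2)[1:4, ]
  rows$maf_A <- c(0.05, 0.3, 0.1, 0.49)
  rows$maf_B <- c(0.2, 0.3, 0.0999, 0.3)
  rows$syntenic <- c(TRUE, TRUE, FALSE, TRUE)
  ms <- mafClassSummary(rows, components = "cld")
  pick <- function(syn, a, b) ms[ms$syntenic == syn & ms$maf_class_A == a &
                                   ms$maf_class_B == b & ms$component == "cld", ]
  expect_identical(pick(TRUE, "[0,0.1)", "[0.1,0.3)")$n_pairs, 1L)
  expect_identical(pick(TRUE, "[0.3,0.5]", "[0.3,0.5]")$n_pairs, 2L)  # 0.3 is upper class
  expect_identical(pick(FALSE, "[0.1,0.3)", "[0,0.1)")$n_pairs, 1L)
})

test_that("the power-distance curve reduces to powerEstimate on one window", {
  rows <- scanPairs(toyPanel(), minN = 2)
  pv <- powerVsDistanceCurve(rows, windowBp = 5e6, maxBp = 5e6,
                             components = "cld")
  keep <- oobFilter(rows$phi2_cld[rows$syntenic])$keep
  direct <- powerEstimate(rows$x2_cld[rows$syntenic][keep])
  expect_equal(pv$power, as.numeric(direct))
})

test_that("summaries recomputed from a persisted TSV are identical", {
  rows <- scanPairs(toyPanel(), minN = 2)
  path <- tempfile(fileext = ".tsv")
  writePairResults(rows, path)
  back <- read.delim(path)
  b1 <- binByDistance(rows)
  b2 <- binByDistance(back)
  expect_equal(b1, b2, tolerance = 1e-12)
})

test_that("admixture panels show the frequency dependence of test power", {
  # moderately differentiated founder lines, unlinked markers: composite-LD
  # power rises with the MAF class of both loci, while the power of the
  # (major-corner) zygotic-LD test falls relative to composite LD
  set.seed(303)
  K <- 12; m <- 120; n <- 1023
  w <- seq(1.3, 0.7, length.out = K); w <- w / sum(w)
  base <- runif(m, 0.03, 0.5)
  pk <- plogis(qlogis(base)[col(matrix(0, K, m))] + 0.6 * matrix(rnorm(K * m), K, m))
  sim <- simulateAdmixture(pk, w, generations = 0, n = n, truth = FALSE)
  rows <- scanPairs(qcFilter(sim$panel)$panel, mode = "nonsyntenic",
                    subsample = 6000, seed = 303, zygotic = "opposite")
  ms <- mafClassSummary(rows, components = c("cld", "zld"))
  diag <- ms[ms$maf_class_A == ms$maf_class_B, ]
  cld <- diag$mean_power[diag$component == "cld"]
  zld <- diag$mean_power[diag$component == "zld"]
  expect_identical(length(cld), 3L)
  expect_true(all(diff(cld) > 0))          # low -> mid -> high MAF
  expect_lt(zld[3] / cld[3], zld[2] / cld[2])
})
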