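test_that("dosage tables decode codes, missing tokens and unmapped markers", {
  geno <- tempfile(fileext = ".tsv"); mapf <- tempfile(fileext = ".tsv")
  writeLines(c("animal_id\tm1\tm2",
               "an1\t0\t2",
               "an2\t1\tNA"), geno)
  writeLines(c("marker_id\tchrom\tpos_bp",
               "m1\t1\t100"), mapf)
  p <- readDosageTable(geno, mapf)
  d <- dosages(p)
  expect_identical(d["an1", "m1"], 0L)
  expect_identical(d["an2", "m1"], 1L)
  expect_identical(d["an1", "m2"], 2L)
  expect_true(is.na(d["an2", "m2"]))
  # m2 absent from the map: loaded but unmapped
  mp <- markerMap(p)
  expect_identical(mp$chrom[mp$marker_id == "m2"], "unknown")
})

test_that("dosage reader rejects malformed input", {
  geno <- tempfile()
  writeLines(c("animal_id\tm1\tm2", "an1\t0\t3"), geno)
  expect_error(readDosageTable(geno), "non-dosage")
  writeLines(c("animal_id\tm1\tm2", "an1\t0"), geno)
  expect_error(readDosageTable(geno))
  writeLines(c("animal_id\tm1\tm1", "an1\t0\t1"), geno)
  expect_error(readDosageTable(geno), "duplicate marker")
})

test_that("write -> read round-trips the panel exactly", {
  set.seed(41)
  d <- matrix(sample(c(0:2, NA), 60, replace = TRUE), 10, 6,
              dimnames = list(paste0("an", 1:10), paste0("m", 1:6)))
  map <- data.frame(marker_id = paste0("m", 1:6),
                    chrom = rep(c("1", "2"), each = 3),
                    pos_bp = c(10, 20, 30, 10, 20, 30) * 1e5)
  p <- GenotypePanel(d, map)
  geno <- tempfile(); mapf <- tempfile()
  writeDosageTable(p, geno, mapf)
  p2 <- readDosageTable(geno, mapf)
  expect_identical(dosages(p2), dosages(p))
  expect_equal(markerMap(p2), markerMap(p))
})

test_that("PLINK text dialect: minor-by-label A allele, missing and errors", {
  ped <- tempfile(); mapf <- tempfile()
  writeLines("FAM1 IND1 0 0 1 -9 A A G T", ped)
  writeLines(c("1 m1 0 100", "1 m2 0 200"), mapf)
  p <- readPlinkText(ped, mapf)
  # m1: alleles {A}; A designated -> dosage 2. m2: {G,T}, G < T -> dosage of G = 1
  expect_identical(as.integer(dosages(p)["IND1", c("m1", "m2")]), c(2L, 1L))
  expect_identical(unname(p@metadata$a_allele[["m2"]]), "G")

  writeLines(c("FAM1 IND1 0 0 1 -9 0 A C C",
               "FAM1 IND2 0 0 1 -9 A A C G"), ped)
  p <- readPlinkText(ped, mapf)
  expect_true(is.na(dosages(p)["IND1", "m1"]))  # half-missing pair -> NA

  writeLines(c("FAM1 IND1 0 0 1 -9 A A C C",
               "FAM1 IND2 0 0 1 -9 A A G T",
               "FAM1 IND3 0 0 1 -9 A A A C"), ped)
  expect_error(readPlinkText(ped, mapf), "m2")

  writeLines("FAM1 IND1 0 0 1 -9 A A G", ped)
  expect_error(readPlinkText(ped, mapf))
})

test_that("VCF genotypes map GT to ALT dosage with ./. missing", {
  skip_if_not_installed("vcfR")
  vcf <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tan1\tan2",
    "1\t100\trs1\tA\tG\t.\tPASS\t.\tGT\t0/1\t1|1",
    "1\t200\trs2\tC\tT\t.\tPASS\t.\tGT\t./.\t0/0"), vcf)
  p <- readVcfGenotypes(vcf)
  d <- dosages(p)
  expect_identical(as.integer(d[c("an1", "an2"), "rs1"]), c(1L, 2L))
  expect_true(is.na(d["an1", "rs2"]))
  expect_identical(as.integer(d["an2", "rs2"]), 0L)
})

test_that("QC removes markers in the documented rule order with exact tallies", {
  set.seed(42)
  n <- 100
  d <- cbind(
    mono = rep(2L, n),                                    # rule i
    unmap = rbinom(n, 2, 0.3),                            # rule ii
    sexm = rbinom(n, 2, 0.3),                             # rule iii
    rare = c(rep(1L, 2), rep(0L, n - 2)),                 # MAF 0.01 -> rule iv
    okmaf = c(rep(1L, 10), rep(0L, n - 10)),              # MAF 0.05 -> kept
    hwd = c(rep(2L, 50), rep(0L, 50)),                    # f=1, X2=100 -> kept
    good = rbinom(n, 2, 0.4))
  rownames(d) <- paste0("an", 1:n)
  map <- data.frame(marker_id = colnames(d)[-2],
                    chrom = c("1", "X", "1", "1", "1", "1"),
                    pos_bp = 1:6 * 1000)
  panel <- GenotypePanel(d, map)
  res <- qcFilter(panel)
  r <- res$report
  expect_identical(unname(r@removed["monomorphic"]), 1L)
  expect_identical(unname(r@removed["unmapped"]), 1L)
  expect_identical(unname(r@removed["sex_chromosome"]), 1L)
  expect_identical(unname(r@removed["maf"]), 1L)
  expect_identical(unname(r@removed["hwd"]), 0L)  # n f^2 = 100 <= 600
  expect_identical(r@nInput - sum(r@removed), r@nRetained)
  expect_setequal(markerIds(res$panel), c("okmaf", "hwd", "good"))
  # a truly extreme HWD marker is removed by rule v
  d2 <- cbind(d, hwdbad = rep(c(2L, 0L), n / 2))
  m2 <- rbind(map, data.frame(marker_id = "hwdbad", chrom = "1", pos_bp = 7000))
  r2 <- qcFilter(GenotypePanel(d2, m2), hwdChisqMax = 50)$report
  expect_identical(unname(r2@removed["hwd"]), 2L)  # hwd (X2=100) and hwdbad
})

test_that("QC is idempotent and MAF threshold is strict", {
  set.seed(7)
  d <- matrix(rbinom(500 * 20, 2, runif(20, 0.05, 0.5)[rep(1:20, each = 500)]),
              500, 20, dimnames = list(paste0("an", 1:500), paste0("m", 1:20)))
  map <- data.frame(marker_id = paste0("m", 1:20), chrom = "1",
                    pos_bp = 1:20 * 1e5)
  once <- qcFilter(GenotypePanel(d, map))
  twice <- qcFilter(once$panel)
  expect_identical(sum(twice$report@removed), 0L)
  expect_identical(dosages(twice$panel), dosages(once$panel))

  # MAF exactly at the threshold is removed; just above is retained
  n <- 200
  exact <- c(rep(1L, 8), rep(0L, n - 8))       # MAF 0.02
  above <- c(rep(1L, 9), rep(0L, n - 9))       # MAF 0.0225
  d3 <- cbind(exact = exact, above = above, filler = rbinom(n, 2, 0.5))
  rownames(d3) <- paste0("an", 1:n)
  m3 <- data.frame(marker_id = colnames(d3), chrom = "1", pos_bp = 1:3 * 100)
  kept <- markerIds(qcFilter(GenotypePanel(d3, m3))$panel)
  expect_false("exact" %in% kept)
  expect_true("above" %in% kept)
})

test_that("QC re-orients dosages so the designated allele is minor", {
  n <- 100
  d <- cbind(major = c(rep(2L, 80), rep(1L, 15), rep(0L, 5)),
             minor = c(rep(0L, 80), rep(1L, 15), rep(2L, 5)))
  rownames(d) <- paste0("an", 1:n)
  map <- data.frame(marker_id = colnames(d), chrom = "1", pos_bp = c(1, 2))
  out <- qcFilter(GenotypePanel(d, map))$panel
  ls <- locusSummaries(out)
  expect_true(all(ls$p_A <= 0.5))
  expect_true(out@metadata$flipped[["major"]])
  expect_false(out@metadata$flipped[["minor"]])
})
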