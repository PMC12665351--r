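test_that("call-rate filter removes markers then individuals, strict below", {
  set.seed(1)
  n <- 100
  dos <- matrix(rbinom(n * 4, 2, 0.4), n, 4)
  dos[1:11, 1] <- NA            # marker 1: call rate 0.89 -> removed
  dos[1:10, 2] <- NA            # marker 2: call rate 0.90 -> retained
  g <- make_geno(dos)
  gf <- filter_call_rate(g, 0.90)
  expect_equal(colnames(gf$dosages), c("m2", "m3", "m4"))

  # an individual missing half the retained markers is removed
  dos2 <- matrix(rbinom(40 * 10, 2, 0.4), 40, 10)
  dos2[1, 1:5] <- NA
  g2 <- filter_call_rate(make_geno(dos2), 0.90)
  expect_equal(nrow(g2$dosages), 39)

  # fully observed panel is untouched
  g3 <- filter_call_rate(make_geno(matrix(1, 5, 3)), 0.90)
  expect_equal(dim(g3$dosages), c(5L, 3L))
  expect_true(all(qc_report(g3)$removed == 0))
})

test_that("MAF filter uses frequencies from non-missing calls", {
  dos <- cbind(c(0, 0, 1, 2),     # p = 3/8 = 0.375 -> kept
               c(0, 0, 0, 0),     # monomorphic -> removed
               c(2, 2, 2, 1))     # p = 7/8, maf = 0.125 -> kept at 0.01
  g <- filter_maf(make_geno(dos), 0.01)
  expect_equal(colnames(g$dosages), c("m1", "m3"))

  # frequency just under the threshold is removed: p = 0.995 -> maf 0.005
  dos2 <- cbind(c(rep(2, 99), 1), rbinom(100, 2, 0.5))
  g2 <- filter_maf(make_geno(dos2), 0.01)
  expect_equal(colnames(g2$dosages), "m2")

  # all-missing marker removed with its own reason code
  dos3 <- cbind(rep(NA_real_, 4), c(0, 1, 1, 2))
  rep3 <- qc_report(filter_maf(make_geno(dos3), 0.01))
  expect_equal(rep3$removed[rep3$stage == "all_missing"], 1L)
})

test_that("heterozygosity filter compares observed with 2p(1-p)", {
  het_marker <- function(n0, n1, n2) c(rep(0, n0), rep(1, n1), rep(2, n2))
  dos <- cbind(het_marker(3, 5, 2),   # p=0.45, exp 0.495, obs 0.5 -> kept
               het_marker(1, 8, 1),   # p=0.5, obs 0.8, dev 0.3 -> removed
               het_marker(5, 0, 5))   # p=0.5, obs 0, dev 0.5 -> removed
  g <- filter_het_deviation(make_geno(dos), 0.15)
  expect_equal(colnames(g$dosages), "m1")
})

test_that("het filter keeps essentially everything on HWE data", {
  set.seed(2)
  n <- 600; m <- 300
  p <- runif(m, 0.05, 0.5)
  dos <- matrix(rbinom(n * m, 2, rep(p, each = n)), n, m)
  dos[runif(length(dos)) < 0.01] <- NA
  g <- filter_het_deviation(make_geno(dos), 0.15)
  expect_equal(ncol(g$dosages), m)
})

test_that("position filter drops missing coordinates and keeps first duplicate", {
  dos <- matrix(rbinom(5 * 4, 2, 0.5), 5, 4)
  g <- genotypes(dos, tibble::tibble(
    marker = paste0("m", 1:4),
    chrom = c("chr1", "chr1", "chr1", "chr2"),
    pos = c(1000, 1000, NA, 500)))
  gf <- filter_positions(g)
  expect_equal(gf$map$marker, c("m1", "m4"))
  rep <- qc_report(gf)
  expect_equal(rep$removed[rep$stage == "missing_position"], 1L)
  expect_equal(rep$removed[rep$stage == "duplicated_position"], 1L)
})

test_that("unphenotyped individuals are dropped by exact id match", {
  dos <- matrix(rbinom(10 * 5, 2, 0.5), 10, 5,
                dimnames = list(paste0("sow", 1:10), NULL))
  g <- make_geno(dos)
  gf <- drop_unphenotyped(g, paste0("sow", 1:8))
  expect_equal(nrow(gf$dosages), 8)
  # whitespace variants do not silently match
  gf2 <- drop_unphenotyped(g, c("sow1 ", paste0("sow", 2:10)))
  expect_false("sow1" %in% rownames(gf2$dosages))
  expect_error(drop_unphenotyped(g, "nobody"), "no genotyped")
})

test_that("the full QC pipeline is idempotent and its report reconciles", {
  set.seed(3)
  n <- 120; m <- 80
  p <- runif(m, 0.005, 0.5)
  dos <- matrix(rbinom(n * m, 2, rep(p, each = n)), n, m)
  dos[sample(length(dos), 400)] <- NA
  geno <- genotypes(dos, tibble::tibble(
    marker = paste0("m", 1:m),
    chrom = rep(c("chr1", "chr2"), each = m / 2),
    pos = c(1:(m / 2) * 100, c(100, 100, 3:(m / 2) * 100))))
  once <- run_qc(geno)
  rep1 <- qc_report(once)
  # removals reconcile with the dimension track at every stage
  mk <- rep1[rep1$axis == "markers", ]
  expect_equal(mk$n_markers, m - cumsum(mk$removed))
  ind <- rep1[rep1$axis == "individuals", ]
  expect_equal(ind$n_individuals, n - cumsum(ind$removed))
  # applying QC again changes nothing
  twice <- run_qc(once)
  expect_equal(twice$dosages, once$dosages)
  expect_true(all(qc_report(twice)$removed[-seq_len(nrow(rep1))] == 0))
})

test_that("plink text files round-trip dosages up to allele orientation", {
  set.seed(4)
  dos <- matrix(rbinom(12 * 6, 2, 0.5), 12, 6,
                dimnames = list(sprintf("sow%02d", 1:12), NULL))
  dos[2, 3] <- NA
  g <- make_geno(dos)
  prefix <- file.path(withr::local_tempdir(), "panel")
  write_plink_ped(g, prefix)
  back <- read_plink_ped(prefix)
  expect_equal(dim(back$dosages), dim(g$dosages))
  expect_equal(back$map$pos, g$map$pos)
  for (j in seq_len(ncol(dos))) {
    d0 <- g$dosages[, j]; d1 <- back$dosages[, j]
    expect_true(isTRUE(all.equal(d0, d1, check.attributes = FALSE)) ||
                  isTRUE(all.equal(2 - d0, d1, check.attributes = FALSE)))
  }
})
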