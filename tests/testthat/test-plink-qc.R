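make_ped_map_fixture <- function(dir) {
  ## 2 individuals x 3 SNPs, hand-written
  writeLines(c(
    "FAM ind1 0 0 1 -9 A A A G G G",
    "FAM ind2 0 0 2 -9 A T G G 0 0"
  ), file.path(dir, "toy.ped"))
  writeLines(c(
    "1\tsnp1\t0\t1000",
    "1\tsnp2\t0\t2000",
    "2\tsnp3\t0\t500"
  ), file.path(dir, "toy.map"))
  file.path(dir, "toy")
}

test_that("text PED/MAP reads to the expected dosage matrix", {
  dir <- withr::local_tempdir()
  prefix <- make_ped_map_fixture(dir)
  gd <- read_plink_text(paste0(prefix, ".ped"), paste0(prefix, ".map"))
  expect_equal(dim(gd$G), c(2L, 3L))
  expect_equal(rownames(gd$G), c("ind1", "ind2"))
  ## snp1: alleles A,T; minor = T; ind1 AA -> 0, ind2 AT -> 1
  expect_equal(unname(gd$G[, "snp1"]), c(0L, 1L))
  ## snp2: minor allele A; ind1 AG -> 1, ind2 GG -> 0
  expect_equal(unname(gd$G[, "snp2"]), c(1L, 0L))
  expect_equal(gd$map$snp_id, c("snp1", "snp2", "snp3"))
  ## snp3 missing for ind2
  expect_true(is.na(gd$G[2, "snp3"]))
  ## invalid allele codes are a hard error
  writeLines("FAM x 0 0 1 -9 A A A G Z Z",
             file.path(dir, "bad.ped"))
  expect_error(read_plink_text(file.path(dir, "bad.ped"),
                               paste0(prefix, ".map")), "allele")
})

test_that("text and binary PLINK round trips preserve the data", {
  set.seed(42)
  G <- matrix(sample(c(0:2, NA), 15 * 7, replace = TRUE), 7, 15)
  rownames(G) <- sprintf("an%02d", 1:7)
  gd <- make_gd(G, chr = rep(c("1", "2", "3"), each = 5),
                bp = rep(seq(1e5, 5e5, 1e5), 3))
  gd$map$allele1 <- "A"; gd$map$allele2 <- "G"
  dir <- withr::local_tempdir()
  ## text round trip
  write_plink_text(gd, file.path(dir, "t"))
  back <- read_plink_text(file.path(dir, "t.ped"), file.path(dir, "t.map"))
  ## counted allele may flip where A is not the minor allele; compare
  ## genotype identity up to orientation
  for (j in seq_len(ncol(G))) {
    same <- identical(unname(back$G[, j]), unname(G[, j]))
    flipped <- identical(unname(back$G[, j]), unname(2L - G[, j]))
    expect_true(same || flipped)
  }
  ## binary round trip is exact
  write_plink_bed(gd, file.path(dir, "b"))
  back2 <- read_plink_bed(file.path(dir, "b"))
  expect_equal(unname(back2$G), unname(G))
  expect_equal(back2$map$bp, gd$map$bp)
  ## read_genotypes dispatches on available files
  expect_equal(unname(read_genotypes(file.path(dir, "b"))$G), unname(G))
})

test_that("exact HWE test matches an independent log-factorial oracle", {
  cases <- list(c(50, 25, 25), c(10, 1, 89), c(0, 10, 90), c(60, 5, 35),
                c(21, 10, 69), c(2, 49, 49))
  for (cs in cases) {
    expect_equal(hwe_exact_test(cs[1], cs[2], cs[3]),
                 oracle_hwe(cs[1], cs[2], cs[3]), tolerance = 1e-9)
  }
  ## balanced HWE counts are not significant
  expect_gt(hwe_exact_test(50, 25, 25), 0.5)
  ## gross heterozygote deficit at common frequency is
  expect_lt(hwe_exact_test(0, 50, 50), 1e-6)
})

test_that("QC filters honour thresholds, order and idempotence", {
  set.seed(7)
  n <- 100L
  G <- cbind(
    rbinom(n, 2, 0.3),                      # clean
    rbinom(n, 2, 0.005),                    # MAF < 0.01 -> dropped
    rbinom(n, 2, 0.4),                      # call-rate boundary (below)
    c(rep(0L, 50), rep(2L, 50)),            # extreme HWE deviation
    rbinom(n, 2, 0.25)                      # clean
  )
  G[1:10, 3] <- NA                          # call rate exactly 0.90
  gd <- make_gd(G, chr = rep("1", 5), bp = (1:5) * 1e5)
  res <- qc_filter(gd)
  expect_equal(res$report$n_input, 5L)
  expect_true("m0002" %in% res$report$dropped_maf)
  ## the 0.90 boundary itself is dropped ("call rate <= 0.90")
  expect_true("m0003" %in% res$report$dropped_callrate)
  expect_true("m0004" %in% res$report$dropped_hwe)
  expect_equal(res$report$n_after_hwe, 2L)
  ## counts reconcile along the chain
  expect_equal(res$report$n_input - length(res$report$dropped_maf),
               res$report$n_after_maf)
  ## idempotence
  res2 <- qc_filter(res$gd)
  expect_equal(res2$gd$map$snp_id, res$gd$map$snp_id)
  expect_error(qc_filter(make_gd(matrix(rbinom(100, 2, 0.001), 100, 1),
                                 "1", 1e5)), "every locus")
})

test_that("autosome filter keeps only configured chromosomes", {
  G <- matrix(rbinom(60, 2, 0.5), 10, 6)
  gd <- make_gd(G, chr = c("1", "1", "2", "X", "33", "2"),
                bp = c(1, 2, 1, 1, 1, 5) * 1e5)
  out <- autosome_filter(gd, autosome_labels = as.character(1:31))
  expect_equal(out$map$chr, c("1", "1", "2", "2"))
  ## all-autosome input unchanged
  gd2 <- make_gd(G[, 1:3], chr = c("1", "2", "3"), bp = c(1, 1, 1) * 1e5)
  expect_equal(autosome_filter(gd2)$map$snp_id, gd2$map$snp_id)
})
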