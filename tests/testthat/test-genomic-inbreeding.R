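test_that("excess-homozygosity inbreeding matches direct evaluation", {
  ## hand dataset: 4 individuals x 5 loci
  G <- rbind(c(0, 0, 2, 2, 0),
             c(1, 1, 1, 1, 1),
             c(0, 1, 2, 0, 2),
             c(2, 2, 2, NA, 0))
  rownames(G) <- paste0("i", 1:4)
  gd <- make_gd(G, chr = rep("1", 5), bp = (1:5) * 5e4)
  ht <- het_inbreeding(gd)
  ## direct spreadsheet-style recomputation
  for (j in 1:5) {
    nm <- sum(!is.na(G[, j]))
    p <- sum(G[, j], na.rm = TRUE) / (2 * nm)
    e <- 1 - 2 * p * (1 - p) * (2 * nm / (2 * nm - 1))
    assign(paste0("e", j), e)
  }
  e_i1 <- e1 + e2 + e3 + e4 + e5
  expect_equal(ht$e_hom[1], e_i1, tolerance = 1e-12)
  expect_equal(ht$F_het[1], (5 - e_i1) / (5 - e_i1), tolerance = 1e-12)
  expect_equal(ht$F_het[1], 1)            # fully homozygous individual
  expect_lt(ht$F_het[2], 0)               # fully heterozygous individual
  e_i4 <- e1 + e2 + e3 + e5
  expect_equal(ht$F_het[4], (4 - e_i4) / (4 - e_i4))
  expect_equal(ht$n_nonmissing[4], 4)
})

test_that("mean excess-homozygosity is near zero under random mating", {
  set.seed(11)
  gd <- hwe_genotypes(300, runif(800, 0.1, 0.9), seed = 11)
  ht <- het_inbreeding(gd)
  se <- sd(ht$F_het) / sqrt(nrow(ht))
  expect_lt(abs(mean(ht$F_het)), 3 * se + 1e-3)
})

test_that("ROH detection handles constructed positives and negatives", {
  par <- roh_params()
  ## all-heterozygous individual: no segments
  G <- matrix(1L, 1, 40)
  rownames(G) <- "het"
  gd <- make_gd(G, chr = rep("1", 40), bp = (1:40) * 5e4)
  expect_equal(nrow(detect_roh(gd, par)), 0L)
  ## 20 homozygous SNPs spanning 600 kb + heterozygous flanks
  g <- c(1L, rep(0L, 20), 1L)
  pos <- c(1e5, seq(2e5, 8e5, length.out = 20), 9e5)
  G2 <- matrix(g, 1); rownames(G2) <- "hom"
  gd2 <- make_gd(G2, chr = rep("1", 22), bp = round(pos))
  segs <- detect_roh(gd2, par)
  expect_equal(nrow(segs), 1L)
  expect_equal(segs$n_snps, 20L)
  expect_equal(segs$start_bp, 2e5)
  expect_equal(segs$end_bp, 8e5)
  expect_equal(segs$length_bp, 6e5)
  expect_equal(segs$n_het, 0L)
})

test_that("every emitted segment satisfies all run criteria", {
  par <- roh_params(min_snps = 10L, min_length_bp = 3e5)
  set.seed(21)
  G <- matrix(sample(c(0L, 1L, 2L, NA), 3 * 400, replace = TRUE,
                     prob = c(0.55, 0.06, 0.35, 0.04)), 3, 400)
  rownames(G) <- paste0("i", 1:3)
  gd <- make_gd(G, chr = rep(c("1", "2"), each = 200),
                bp = rep(cumsum(sample(2e4:9e4, 200)), 2))
  segs <- detect_roh(gd, par)
  expect_gt(nrow(segs), 0L)
  expect_true(all(segs$n_snps >= par$min_snps))
  expect_true(all(segs$length_bp >= par$min_length_bp))
  expect_true(all(segs$n_het <= par$max_het))
  expect_true(all(segs$n_missing <= par$max_missing))
  expect_true(all(segs$n_snps * par$density_bp_per_snp >= segs$length_bp))
})

test_that("ROH detection equals the brute-force maximal-interval oracle", {
  par <- roh_params(min_snps = 6L, min_length_bp = 2.5e5, max_gap_bp = 4e5,
                    density_bp_per_snp = 1e5)
  for (s in 1:15) {
    set.seed(400 + s)
    L <- 80L
    pos <- sort(sample(seq(1e4, 6e6, by = 1e4), L))
    g <- sample(c(0L, 1L, 2L, NA), L, replace = TRUE,
                prob = c(0.44, 0.09, 0.43, 0.04))
    got <- herdvar:::scan_runs(g, pos, par)
    want <- oracle_roh(g, pos, par)
    expect_equal(unname(got), unname(want), info = paste("seed", 400 + s))
  }
})

test_that("F_roh arithmetic and defaults are correct", {
  segs <- data.frame(id = c("a", "a", "b"), chr = "1",
                     start_bp = c(1e6, 5e6, 1e6), end_bp = c(2e6, 6e6, 1.5e6),
                     n_snps = 20L, n_het = 0L, n_missing = 0L,
                     length_bp = c(1e6, 1e6, 5e5))
  fr <- froh(segs, ids = c("a", "b", "c"), L_auto_bp = 1e7)
  expect_equal(fr$f_roh, c(0.2, 0.05, 0))
  expect_error(froh(segs, c("a"), 0), "positive")
  ## total 227.6 on 2276 -> 0.10
  segs2 <- data.frame(id = "x", chr = "1", start_bp = 0, end_bp = 227.6e6,
                      n_snps = 10L, n_het = 0L, n_missing = 0L,
                      length_bp = 227.6e6)
  expect_equal(froh(segs2, "x", 2276e6)$f_roh, 0.1)
  ## map span: first-to-last SNP per chromosome, summed
  map <- data.frame(chr = c("1", "1", "2", "2"), bp = c(100, 600, 50, 250))
  expect_equal(map_span_bp(map), 500 + 200)
})

test_that("length classes use left-open right-closed Mb bins", {
  mk <- function(len_mb, id = "a")
    data.frame(id = id, chr = "1", start_bp = 0, end_bp = len_mb * 1e6,
               n_snps = 0L, n_het = 0L, n_missing = 0L,
               length_bp = len_mb * 1e6)
  segs <- do.call(rbind, list(mk(0.9), mk(1.1), mk(1.0), mk(13.61, "b"),
                              mk(3), mk(5, "b"), mk(7.9, "c"), mk(0.6, "c"),
                              mk(2.0), mk(16, "b")))
  tab <- roh_class_stats(segs)
  expect_equal(tab$class, c("0-1", "1-2", "2-4", "4-8", ">8"))
  ## 1.0 falls in (0,1], 2.0 in (1,2]
  expect_equal(tab$n_roh, c(3L, 2L, 1L, 2L, 2L))
  expect_equal(sum(tab$n_roh), nrow(segs))
  expect_equal(sum(tab$pct_n_roh), 1)
  expect_equal(tab$l_roh_mb[tab$class == ">8"], mean(c(13.61, 16)))
  expect_equal(tab$n_individuals[tab$class == ">8"], 1L)
  expect_equal(tab$s_roh[tab$class == ">8"], 2)
})
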