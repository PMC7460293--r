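test_that("pedigree construction validates ids, cycles and sex roles", {
  ped <- pedigree(c("A", "B", "C"), c(NA, NA, "A"), c(NA, NA, "B"),
                  c(2000, 2000, 2010), c("M", "F", "M"))
  expect_s3_class(ped, "herd_pedigree")
  expect_equal(nrow(ped), 3L)
  expect_true(all(match(ped$sire, ped$id, nomatch = 0L) <
                    seq_len(nrow(ped)) | is.na(ped$sire)))

  expect_error(pedigree(c("A", "A"), c(NA, NA), c(NA, NA)), "duplicate")
  expect_error(pedigree(c("X", "Y"), c("Y", "X"), c(NA, NA)), "cycle")
  ## a known male used as dam is a hard error
  expect_error(pedigree(c("A", "B", "C"), c(NA, NA, "B"), c(NA, NA, "A"),
                        sex = c("M", "M", "M")), "sex-inconsistent")
  ## unknown-sex animal in both roles (selfing) is allowed with a warning
  expect_warning(pedigree(c("A", "B"), c(NA, "A"), c(NA, "A"),
                          sex = c("U", "U")), "both sire and dam")
})

test_that("file order does not matter and parents may be implicit", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,sire,dam,birth_year,sex,origin",
               "C,A,B,2010,M,native",
               "A,0,0,2000,M,native",
               "B,0,0,2000,F,native"), f)
  ped <- read_pedigree(f)
  expect_equal(sort(ped$id), c("A", "B", "C"))
  expect_lt(match("A", ped$id), match("C", ped$id))
  ## both "0" and empty string mean unknown
  f2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,sire,dam", "A,0,", "B,,0", "C,A,B"), f2)
  ped2 <- read_pedigree(f2)
  expect_equal(sum(ped2$sire_idx == 0L & ped2$dam_idx == 0L), 2L)
})

test_that("written pedigrees read back identically", {
  ped <- rand_pedigree(40, seed = 5, p_unknown = 0.2)
  f <- withr::local_tempfile(fileext = ".csv")
  write_pedigree(ped, f)
  back <- read_pedigree(f)
  expect_equal(back$id, ped$id)
  expect_equal(back$sire, ped$sire)
  expect_equal(back$dam, ped$dam)
  expect_equal(back$birth_year, ped$birth_year)
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_pedigree(back, f2)
  expect_identical(readLines(f), readLines(f2))
})

test_that("parent-younger-than-child is flagged, strict mode drops it", {
  expect_warning(
    ped <- pedigree(c("A", "B", "C"), c(NA, NA, "A"), c(NA, NA, "B"),
                    c(2010, 2000, 2005), c("M", "F", "M")),
    "parent not older")
  expect_true(any(ped$flag_year))
  suppressWarnings(
    ped2 <- pedigree(c("A", "B", "C"), c(NA, NA, "A"), c(NA, NA, "B"),
                     c(2010, 2000, 2005), c("M", "F", "M"), strict = TRUE))
  expect_false("C" %in% ped2$id[ped2$flag_year])
})

test_that("completeness index weights yearly fractions by cohort size", {
  ## all parents known -> 1
  ped <- pedigree(c("A", "B", "C", "D"), c(NA, NA, "A", "A"),
                  c(NA, NA, "B", "B"), c(1990, 1990, 2000, 2000))
  pc <- pedigree_completeness(ped)
  expect_equal(pc$per_year$pc[pc$per_year$birth_year == 2000], 1.0)
  ## one complete + one unknown animal in a year -> 0.5
  ped2 <- pedigree(c("A", "B", "C", "D"), c(NA, NA, "A", NA),
                   c(NA, NA, "B", NA), c(1990, 1990, 2000, 2000))
  pc2 <- pedigree_completeness(ped2)
  expect_equal(pc2$per_year$pc[pc2$per_year$birth_year == 2000], 0.5)
  ## weighted mean: 2000 (4 born, PC 1) and 2001 (1 born, PC 0) -> 0.8
  ped3 <- pedigree(
    c("S", "D", paste0("k", 1:4), "u"),
    c(NA, NA, rep("S", 4), NA), c(NA, NA, rep("D", 4), NA),
    c(1990, 1990, rep(2000, 4), 2001))
  pc3 <- pedigree_completeness(ped3)
  yr <- pc3$per_year[pc3$per_year$birth_year %in% c(2000, 2001), ]
  expect_equal(yr$pc, c(1, 0))
  expect_equal(sum(yr$pc * yr$n_born) / sum(yr$n_born), 0.8)
  expect_error(pedigree_completeness(ped3[0, ]), "empty")
})

test_that("equivalent generations match closed forms and path enumeration", {
  ## two known parents, unknown grandparents -> 1
  ped <- pedigree(c("A", "B", "C"), c(NA, NA, "A"), c(NA, NA, "B"))
  expect_equal(unname(equivalent_generations(ped)["C"]), 1.0)
  ## full two-generation pedigree -> 2
  ped2 <- pedigree(c("G1", "G2", "G3", "G4", "P1", "P2", "K"),
                   c(NA, NA, NA, NA, "G1", "G3", "P1"),
                   c(NA, NA, NA, NA, "G2", "G4", "P2"))
  expect_equal(unname(equivalent_generations(ped2)["K"]), 2.0)
  ## one known parent with two known grandparents -> (1 + 1)/2
  ped3 <- pedigree(c("G1", "G2", "P", "K"), c(NA, NA, "G1", "P"),
                   c(NA, NA, "G2", NA))
  expect_equal(unname(equivalent_generations(ped3)["K"]), 1.0)
  ## recursion equals brute-force path enumeration on random pedigrees
  for (s in 1:5) {
    ped <- rand_pedigree(30, seed = s, p_unknown = 0.3)
    eq <- equivalent_generations(ped)
    for (i in c(1L, 10L, 20L, 30L))
      expect_equal(unname(eq[i]), oracle_eqgen(ped, i), tolerance = 1e-12)
  }
})

test_that("generation lengths follow the four gamete pathways", {
  ped <- pedigree(c("S", "D", "a", "b", "c", "d"),
                  c(NA, NA, "S", "S", "S", "S"),
                  c(NA, NA, "D", "D", "D", "D"),
                  c(2000, 2001, 2009, 2009, 2008, 2010),
                  c("M", "F", "M", "M", "M", "M"))
  gl <- generation_lengths(ped)
  ss <- gl[gl$pathway == "SS", ]
  expect_equal(ss$n_pairs, 4L)
  expect_equal(ss$mean, mean(c(9, 9, 8, 10)))
  expect_equal(ss$sd, sd(c(9, 9, 8, 10)))
  ds <- gl[gl$pathway == "DS", ]
  expect_equal(ds$mean, mean(c(8, 8, 7, 9)))
  ## no daughters: DD empty but not an error
  expect_equal(gl$n_pairs[gl$pathway == "DD"], 0L)
  expect_true(is.na(gl$mean[gl$pathway == "DD"]))
})

test_that("reference population filters by year window and origin", {
  ped <- pedigree(sprintf("A%02d", 1:10), rep(NA, 10), rep(NA, 10),
                  c(rep(2005, 3), rep(2012, 4), rep(2015, 3)),
                  origin = c(rep("native", 8), "imported", "imported"))
  ref <- reference_population(ped, 2010, 2019, exclude_origin = "imported")
  expect_equal(length(ref), 5L)
  expect_true(all(ped$origin[match(ref, ped$id)] == "native"))
  expect_equal(length(reference_population(ped, 2000, 2020)), 10L)
  expect_warning(reference_population(ped, 1900, 1901), "empty")
})
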