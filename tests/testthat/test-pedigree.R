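test_that("pedigree validation handles trios, aliases and sex codes", {
  ped <- ped_trio()
  expect_s3_class(ped, "ped")
  expect_equal(ped$generation, c(0L, 0L, 1L))
  expect_equal(ped$founder, c(TRUE, TRUE, FALSE))

  # FAM-style aliases and numeric sex codes normalise to the same object
  alt <- validate_pedigree(data.frame(
    individual_id = c("F", "M", "C"), father_id = c("0", "0", "F"),
    mother_id = c("0", "0", "M"), sex = c(1, 2, 1)))
  expect_equal(alt$sex, c("male", "female", "male"))
  expect_equal(alt$father, c(NA, NA, "F"))
})

test_that("degenerate pedigrees are rejected with informative errors", {
  expect_error(validate_pedigree(data.frame(
    id = "X", father = "X", mother = NA, sex = 1)), "cycle")
  expect_error(validate_pedigree(data.frame(
    id = c("A", "A"), father = NA, mother = NA, sex = 1)), "duplicate")
  expect_error(validate_pedigree(data.frame(
    id = "A", father = "Z", mother = NA, sex = 1)), "unknown")
  # two-node ancestor loop (neither is a founder)
  expect_error(validate_pedigree(data.frame(
    id = c("A", "B", "M"), father = c("B", "A", NA),
    mother = c("M", "M", NA), sex = c(1, 1, 2))), "cycle")
})

test_that("generations are longest paths from founders on a 20-member pedigree", {
  ped <- ped_toy20()
  expect_equal(stats::setNames(ped$generation, ped$id),
               toy20_expected_generation[ped$id])
})

test_that("numerator relationships match closed forms", {
  ped <- ped_trio()
  A <- additive_relationship(ped)
  expect_equal(A["F", "C"], 0.5)          # parent-offspring
  expect_equal(A["F", "M"], 0)
  expect_equal(diag(A), c(F = 1, M = 1, C = 1))

  sibs <- validate_pedigree(data.frame(
    id = c("F", "M", "S1", "S2"), father = c(NA, NA, "F", "F"),
    mother = c(NA, NA, "M", "M"), sex = c(1, 2, 1, 2)))
  expect_equal(additive_relationship(sibs)["S1", "S2"], 0.5)

  fs <- ped_fullsib_child()
  A <- additive_relationship(fs)
  expect_equal(A["X", "X"], 1.25)         # f = 0.25 from full-sib mating
  expect_equal(pedigree_inbreeding(A)[["X"]], 0.25)

  # hand-traced inbreeding loop in the 20-member pedigree
  A20 <- additive_relationship(ped_toy20())
  expect_equal(A20["D3", "D2"], 0.25)
  expect_equal(A20["E3", "E3"], 1.125)
})

test_that("relationship matrices are symmetric PSD across random pedigrees", {
  for (s in 1:5) {
    ped <- simulate_pedigree(sim_config(seed = s, n_target = 60L), seed = s)
    A <- additive_relationship(ped)
    expect_true(isSymmetric(unname(A)))
    expect_true(all(diag(A) >= 1))
    offdiag <- A[upper.tri(A)]
    expect_true(all(offdiag >= 0 & offdiag <= 2))
    ev <- eigen(A, symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), -1e-8)
  }
})

test_that("excess homozygosity follows the method-of-moments formula", {
  # all-het at p = 0.5: O = 0, E = L/2 -> F = -1; all-hom -> F = 1
  L <- 6
  d <- rbind(het = rep(1, L), hom = rep(c(0, 2), 3))
  F <- excess_homozygosity(d, rep(0.5, L))
  expect_equal(unname(F), c(-1, 1))

  # L = 4, p = 0.5, 3 homozygous loci -> (3 - 2) / (4 - 2) = 0.5
  d1 <- matrix(c(0, 2, 2, 1), 1)
  expect_equal(unname(excess_homozygosity(d1, rep(0.5, 4))), 0.5)

  expect_error(excess_homozygosity(d1, c(0, 0.5, 0.5, 0.5)), "frequencies")
  d2 <- rbind(d1, NA)
  expect_warning(F2 <- excess_homozygosity(d2, rep(0.5, 4)), "missing")
  expect_true(is.na(F2[2]))
})

test_that("Hardy-Weinberg genotypes have mean F near zero", {
  set.seed(42)
  L <- 2000; n <- 80
  p <- runif(L, 0.1, 0.9)
  d <- sapply(p, function(pp) stats::rbinom(n, 2, pp))
  F <- excess_homozygosity(d, p)
  se <- stats::sd(F) / sqrt(n)
  expect_lt(abs(mean(F)), 3 * se)
})

test_that("nuclear families match exhaustive parent-pair enumeration", {
  expect_length(extract_nuclear_families(ped_trio()), 1)

  # father with children by two mothers -> two families
  ped2 <- validate_pedigree(data.frame(
    id = c("F", "M1", "M2", "C1", "C2"), father = c(NA, NA, NA, "F", "F"),
    mother = c(NA, NA, NA, "M1", "M2"), sex = c(1, 2, 2, 1, 1)))
  expect_length(extract_nuclear_families(ped2), 2)

  ped <- ped_toy20()
  fams <- extract_nuclear_families(ped)
  # brute-force oracle: enumerate distinct parent pairs over all children
  both <- !is.na(ped$father) & !is.na(ped$mother)
  pairs <- unique(paste(ped$father[both], ped$mother[both]))
  expect_length(fams, length(pairs))
  for (fam in fams) {
    kids <- ped$id[!is.na(ped$father) & ped$father == fam$father &
                     !is.na(ped$mother) & ped$mother == fam$mother]
    expect_setequal(fam$children, kids)
  }
})

test_that("pioneer-descent flags match hand-traced reachability", {
  ped <- ped_toy20()
  fl <- founder_descendant_flags(ped, c("A1", "A2"))
  in_fam <- fl$id[fl$in_family]
  expect_setequal(in_fam, c("A1", "A2", "C1", "C2", "D1", "D2", "D3", "D4",
                            "E1", "E2", "E3", "G1", "G2"))
  expect_setequal(fl$id[fl$group == "married_in"],
                  c("B1", "B2", "S1", "S2", "S3", "C3", "C4"))
  expect_error(founder_descendant_flags(ped, "nope"), "unknown")
})

test_that("FAM files round-trip", {
  ped <- ped_toy20()
  path <- withr::local_tempfile(fileext = ".fam")
  write_fam(ped, path, phenotype = seq_len(nrow(ped)))
  back <- read_fam(path)
  expect_equal(back$id, ped$id)
  expect_equal(back$father, ped$father)
  expect_equal(back$mother, ped$mother)
  expect_equal(back$sex, ped$sex)
  expect_equal(back$generation, ped$generation)
  expect_equal(attr(back, "phenotype"), seq_len(nrow(ped)))
})
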