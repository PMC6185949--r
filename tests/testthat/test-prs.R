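# A 6-variant toy cohort exercising every harmonisation branch:
# v1 effect=ALT, v2 effect=REF (flip), v3 A/T palindrome, v4 C/G palindrome,
# v5 allele mismatch, v6 matched; plus one sumstats row absent from the
# cohort.
toy_prs_setup <- function() {
  dosage <- rbind(i1 = c(2, 1, 0, 1, 2, 0),
                  i2 = c(0, 2, 1, 1, 0, 1),
                  i3 = c(1, 0, 2, 0, 1, 2),
                  i4 = c(2, 2, 2, 2, 2, 2))
  geno <- make_toy_geno(dosage,
                        ref = c("A", "G", "A", "C", "A", "T"),
                        alt = c("C", "T", "T", "G", "C", "G"),
                        pos = c(1000L, 2000L, 3000L, 4000L, 5000L, 6000L))
  ss <- data.frame(SNP = c("v1", "v2", "v3", "v4", "v5", "v6", "v7"),
                   A1 = c("C", "G", "A", "C", "A", "G", "A"),
                   A2 = c("A", "T", "T", "G", "G", "T", "C"),
                   BETA = c(0.5, 0.4, 0.3, 0.2, 0.1, -0.2, 0.9),
                   SE = 0.1,
                   P = c(0.001, 0.2, 0.5, 0.5, 0.5, 0.04, 0.5),
                   stringsAsFactors = FALSE)
  list(geno = geno, ss = ss)
}

test_that("allele harmonisation orients, flips, and drops correctly", {
  s <- toy_prs_setup()
  w <- align_alleles(s$ss, s$geno)
  expect_setequal(w$id, c("v1", "v2", "v6"))
  expect_equal(w$beta[w$id == "v1"], 0.5)    # effect allele is ALT
  expect_equal(w$beta[w$id == "v2"], -0.4)   # effect allele is REF: flip
  expect_equal(w$beta[w$id == "v6"], -0.2)
  lg <- attr(w, "log")
  expect_equal(unname(lg["palindromic_dropped"]), 2)
  expect_equal(unname(lg["mismatched_dropped"]), 1)
  expect_equal(unname(lg["unmatched"]), 1)

  ss_none <- s$ss[7, , drop = FALSE]
  expect_error(align_alleles(ss_none, s$geno), "harmonised")
})

test_that("greedy clumping matches a brute-force oracle", {
  # v1..v5 with controlled LD: v2 duplicates v1 (r2 = 1), v4 = 2 - v3
  # (r2 = 1 with v3), v5 independent. All within one 250 kb window.
  set.seed(8)
  g1 <- rbinom(40, 2, 0.4)
  g3 <- rbinom(40, 2, 0.5)
  g5 <- rbinom(40, 2, 0.3)
  dosage <- cbind(v1 = g1, v2 = g1, v3 = g3, v4 = 2 - g3, v5 = g5)
  rownames(dosage) <- sprintf("i%d", 1:40)
  geno <- make_toy_geno(dosage, pos = c(1000L, 2000L, 3000L, 4000L, 5000L))
  w <- data.frame(id = colnames(dosage), chrom = "1",
                  pos = c(1000L, 2000L, 3000L, 4000L, 5000L),
                  beta = c(0.1, 0.2, 0.3, 0.4, 0.5),
                  p = c(0.01, 0.002, 0.03, 0.5, 0.2),
                  stringsAsFactors = FALSE)
  class(w) <- c("prs_weights", "data.frame")

  kept <- ld_clump(w, geno, r2_max = 0.1, window_kb = 250)$id

  # independent oracle: literal greedy over the full r2 matrix
  r2 <- stats::cor(dosage)^2
  remaining <- w[order(w$p, w$pos), ]
  expected <- character(0)
  while (nrow(remaining)) {
    idx <- remaining$id[1]
    expected <- c(expected, idx)
    drop <- remaining$id[r2[idx, remaining$id] > 0.1 &
                           abs(remaining$pos - remaining$pos[1]) <= 250000]
    remaining <- remaining[!(remaining$id %in% drop | remaining$id == idx), ]
  }
  expect_setequal(kept, expected)
  expect_setequal(kept, c("v2", "v3", "v5"))

  # mutually uncorrelated variants are all retained
  set.seed(9)
  ind <- sapply(1:5, function(i) rbinom(200, 2, 0.5))
  colnames(ind) <- sprintf("v%d", 1:5)
  rownames(ind) <- sprintf("i%d", 1:200)
  gi <- make_toy_geno(ind, pos = c(1000L, 2000L, 3000L, 4000L, 5000L))
  wi <- w; wi$id <- colnames(ind)
  expect_equal(nrow(ld_clump(wi, gi, r2_max = 0.5)), 5L)

  # permuting input rows leaves the retained set unchanged
  wp <- w[c(4, 2, 5, 1, 3), ]
  expect_setequal(ld_clump(wp, geno, r2_max = 0.1)$id, kept)
})

test_that("genome-wide scores are the weighted dosage sums", {
  dosage <- rbind(i1 = c(2, 1), i2 = c(0, 0), i3 = c(1, 2))
  geno <- make_toy_geno(dosage)
  w <- data.frame(id = c("v1", "v2"), chrom = "1", pos = c(1000L, 2000L),
                  beta = c(0.5, -0.2), p = c(0.001, 0.04))
  prof <- score_genomewide(w, geno, p_threshold = 1)
  expect_equal(prof$raw, c(2 * 0.5 - 0.2, 0, 0.5 - 0.4))
  expect_equal(mean(prof$z), 0)
  expect_equal(sd(prof$z), 1)
  expect_equal(attr(prof, "n_variants"), 2L)

  # single-variant threshold
  prof1 <- score_genomewide(w, geno, p_threshold = 0.01)
  expect_equal(prof1$raw, dosage[, 1] * 0.5, ignore_attr = TRUE)
  expect_error(score_genomewide(w, geno, p_threshold = 1e-6), "threshold")

  # all-zero weights: degenerate standardisation is flagged
  w0 <- w; w0$beta <- 0
  expect_warning(p0 <- score_genomewide(w0, geno), "zero variance")
  expect_true(attr(p0, "degenerate"))
  expect_true(all(p0$raw == 0))

  # missing dosages are imputed at twice the founder frequency
  dm <- dosage; dm[1, 1] <- NA
  gm <- make_toy_geno(dm, founder_freq = c(v1 = 0.25, v2 = 0.5))
  pm <- score_genomewide(w, gm)
  expect_equal(pm$raw[1], 2 * 0.25 * 0.5 - 0.2)
})

test_that("scoring is linear in the weights", {
  st <- get_small_study()
  w <- align_alleles(st$sumstats$bd, st$geno)
  w1 <- w; w1$beta <- w$beta * 0.3
  w2 <- w; w2$beta <- w$beta * -1.1
  ws <- w; ws$beta <- w1$beta + w2$beta
  r1 <- score_genomewide(w1, st$geno)$raw
  r2 <- score_genomewide(w2, st$geno)$raw
  rs <- score_genomewide(ws, st$geno)$raw
  expect_equal(rs, r1 + r2, tolerance = 1e-12)
})

test_that("local block scores decompose the genome-wide score", {
  s <- toy_prs_setup()
  w <- align_alleles(s$ss, s$geno)
  # three blocks: [0,2500) holds v1+v2, [2500,5500) holds v5(mism)/v3/v4,
  # [5500,7000) holds v6; middle block has no harmonised variant for P<=1?
  blocks <- data.frame(block = c("B1", "B2", "B3"), chrom = "1",
                       start = c(0L, 2500L, 5500L),
                       end = c(2500L, 5500L, 7000L))
  lp <- score_local(w, s$geno, blocks)
  expect_equal(lp$n_variants, c(2L, 0L, 1L))
  expect_true(lp$empty[2])
  expect_length(lp$uncovered, 0)

  gw <- score_genomewide(w, s$geno)
  expect_equal(unname(rowSums(lp$raw)), gw$raw, tolerance = 1e-12)

  # a single all-covering block reproduces the genome-wide score exactly
  one <- data.frame(block = "ALL", chrom = "1", start = 0L, end = 10000L)
  lp1 <- score_local(w, s$geno, one)
  expect_equal(unname(lp1$raw[, 1]), gw$raw)

  # variants outside every block are reported
  part <- data.frame(block = "B1", chrom = "1", start = 0L, end = 2500L)
  lpp <- score_local(w, s$geno, part)
  expect_setequal(lpp$uncovered, "v6")
})

test_that("local decomposition holds on the full synthetic study", {
  st <- get_small_study()
  w <- align_alleles(st$sumstats$bd, st$geno)
  lp <- score_local(w, st$geno, st$blocks)
  gw <- score_genomewide(w, st$geno)
  expect_length(lp$uncovered, 0)
  rel <- max(abs(rowSums(lp$raw) - gw$raw)) /
    max(abs(gw$raw))
  expect_lt(rel, 1e-10)
})

test_that("threshold scans are monotone and match direct scoring", {
  st <- get_small_study()
  w <- align_alleles(st$sumstats$bd, st$geno)
  y <- phenotype_model(st$phenotypes, "broad_extended")
  ts <- threshold_scan(w, st$geno, c(0.01, 0.1, 1), y, st$kin_eigen)
  expect_equal(nrow(ts$table), 3L)
  expect_true(all(diff(ts$table$n_variants) >= 0))
  expect_equal(sum(ts$table$best), 1L)

  single <- threshold_scan(w, st$geno, 0.1, y, st$kin_eigen)
  prof <- score_genomewide(w, st$geno, 0.1)
  direct <- fit_lmm_association(y, prof$z, kinship = st$kin_eigen)
  expect_equal(single$table$beta, direct$beta, tolerance = 1e-10)
  expect_equal(single$table$p, direct$p, tolerance = 1e-10)
})
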