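test_that("pedigree growth hits the target size with pioneers and loops", {
  cfg <- sim_config(seed = 5)
  ped <- simulate_pedigree(cfg)
  expect_s3_class(ped, "ped")
  expect_gt(nrow(ped), 0.8 * cfg$n_target)
  expect_lt(nrow(ped), 1.2 * cfg$n_target)
  expect_length(attr(ped, "pioneers"), 2)
  # multigenerational with consanguineous loops -> some inbreeding
  expect_gte(max(ped$generation), 4)
  f <- pedigree_inbreeding(additive_relationship(ped))
  expect_gt(max(f), 0)
})

founder_only_ped <- function(n) {
  validate_pedigree(data.frame(id = sprintf("F%04d", seq_len(n)),
                               father = NA_character_,
                               mother = NA_character_, sex = 1))
}

test_that("founder haplotype frequencies match the binomial expectation", {
  ped <- founder_only_ped(1000)
  v <- data.frame(id = "v1", chrom = "1", pos = 100L, ref = "A", alt = "C",
                  cm = 1e-4, freq = 0.3)
  h <- simulate_founders(ped, v, seed = 9)
  n_f <- sum(ped$founder)
  phat <- mean(c(h$hap1[, 1], h$hap2[, 1]))
  ci <- qnorm(0.995) * sqrt(0.3 * 0.7 / (2 * n_f))
  expect_lt(abs(phat - 0.3), ci)

  # degenerate frequency 0 via clipping bound -> essentially all-reference
  v0 <- v; v0$freq <- 0
  h0 <- simulate_founders(ped, v0, seed = 9)
  expect_equal(sum(h0$hap1) + sum(h0$hap2), 0)
})

test_that("gene dropping is Mendelian and deterministic", {
  ped <- ped_toy20()
  L <- 50
  v <- data.frame(id = sprintf("v%02d", 1:L), chrom = "1",
                  pos = seq(1e6, 50e6, length.out = L),
                  ref = "A", alt = "C", cm = seq(1, 50, length.out = L),
                  freq = 0.4)
  h <- simulate_founders(ped, v, seed = 1)
  g <- gene_drop(ped, h, v, seed = 2)
  expect_s3_class(g, "geno")

  # transmission property: every child allele is one of the parent's
  for (i in which(!ped$founder)) {
    fi <- match(ped$father[i], ped$id)
    mi <- match(ped$mother[i], ped$id)
    expect_true(all(g$haplotypes$pat[i, ] == g$haplotypes$pat[fi, ] |
                      g$haplotypes$pat[i, ] == g$haplotypes$mat[fi, ]))
    expect_true(all(g$haplotypes$mat[i, ] == g$haplotypes$pat[mi, ] |
                      g$haplotypes$mat[i, ] == g$haplotypes$mat[mi, ]))
  }

  # Mendelian closure: fix all founders homozygous ALT -> all dosages 2
  h2 <- list(hap1 = h$hap1 * 0L + 1L, hap2 = h$hap2 * 0L + 1L)
  g2 <- gene_drop(ped, h2, v, seed = 3)
  expect_true(all(g2$dosage == 2))

  # determinism
  g3 <- gene_drop(ped, h, v, seed = 2)
  expect_identical(g$dosage, g3$dosage)

  h_bad <- list(hap1 = h$hap1[-1, ], hap2 = h$hap2[-1, ])
  expect_error(gene_drop(ped, h_bad, v, seed = 2), "founder haplotype")
})

test_that("summary statistics converge to truth and are null-calibrated", {
  cfg <- sim_config(seed = 3, n_variants = 1000L, n_chrom = 2L,
                    n_blocks = 10L)
  v <- pedprs:::.simulate_variants(cfg)
  beta <- stats::setNames(rnorm(nrow(v), 0, 0.02), v$id)

  # zero-noise limit: enormous GWAS recovers the true effects
  ss_inf <- simulate_summary_stats(v, beta, gwas_n = 1e12, seed = 4)
  expect_lt(max(abs(ifelse(ss_inf$A1 == v$alt, ss_inf$BETA, -ss_inf$BETA) -
                      beta)), 1e-3)

  # sign convention: re-orienting reported rows onto ALT recovers one
  # common effect vector regardless of which allele was reported
  expect_true(all(ss_inf$A1 != ss_inf$A2))

  # all-null effects give uniform p-values
  ks <- sapply(1:5, function(s) {
    ss <- simulate_summary_stats(v, beta * 0, gwas_n = 5e4, seed = 100 + s)
    suppressWarnings(stats::ks.test(ss$P, "punif")$p.value)
  })
  expect_gt(max(ks), 0.01)
  expect_gt(mean(ks > 0.01), 0.5)
})

test_that("liability phenotypes respect the threshold model", {
  # all variance components zero and all effects zero -> liability is
  # identically 0, so nobody crosses a threshold above the median
  cfg0 <- sim_config(seed = 6, h2 = 1, prs_effect = 1, prevalence = 0.2)
  st <- get_small_study()
  ke <- st$kin_eigen
  ph0 <- simulate_phenotypes(st$geno, ke, cfg0, st$truth$beta_true$bd * 0,
                             seed = 1)
  expect_true(all(abs(ph0$liability) < 1e-12))
  expect_true(all(ph0$affected == 0))

  # founder (unascertained, non-boosted) prevalence tracks K
  cfgF <- sim_config(seed = 8, prevalence = 0.25, h2 = 0.8, prs_effect = 0)
  pedF <- founder_only_ped(400)
  keF <- kinship_eigen(additive_relationship(pedF))
  phF <- simulate_phenotypes(NULL, keF, cfgF, NULL, seed = 2)
  n <- nrow(pedF)
  ci <- qnorm(0.995) * sqrt(0.25 * 0.75 / n)
  expect_lt(abs(mean(phF$affected) - 0.25), ci)

  # categories nest: narrow subset of broad subset of broad_extended
  ph <- st$phenotypes
  yn <- phenotype_model(ph, "narrow")
  yb <- phenotype_model(ph, "broad")
  ye <- phenotype_model(ph, "broad_extended")
  expect_true(all(yn <= yb) && all(yb <= ye))
  expect_equal(sum(ye), sum(ph$affected))
})

test_that("child liability regresses on mid-parent liability at slope h2", {
  # independent trios: parents unrelated founders, kinship block-diagonal;
  # closed form for the chosen parameterisation: slope = h2 (the full
  # genetic part, true score + background, is transmitted additively)
  cfg <- sim_config(seed = 10, h2 = 0.8, prs_effect = 0)
  n_trio <- 300
  ids <- c(sprintf("F%d", 1:n_trio), sprintf("M%d", 1:n_trio),
           sprintf("C%d", 1:n_trio))
  ped <- validate_pedigree(data.frame(
    id = ids,
    father = c(rep(NA, 2 * n_trio), sprintf("F%d", 1:n_trio)),
    mother = c(rep(NA, 2 * n_trio), sprintf("M%d", 1:n_trio)),
    sex = c(rep(1, n_trio), rep(2, n_trio), rep(1, n_trio))))
  ke <- kinship_eigen(additive_relationship(ped))
  ph <- simulate_phenotypes(NULL, ke, cfg, NULL, seed = 3)
  liab <- stats::setNames(ph$liability, ph$id)
  mid <- (liab[sprintf("F%d", 1:n_trio)] + liab[sprintf("M%d", 1:n_trio)]) / 2
  slope <- stats::coef(stats::lm(liab[sprintf("C%d", 1:n_trio)] ~ mid))[2]
  expect_lt(abs(slope - 0.8), 0.1)
})

test_that("Mendelian injection transmits along pedigree paths", {
  ped <- ped_toy20()
  L <- 20
  v <- data.frame(id = sprintf("v%02d", 1:L), chrom = "1",
                  pos = seq(2e6, 40e6, length.out = L), ref = "A",
                  alt = "C", cm = seq(2, 40, length.out = L), freq = 0.4)
  h <- simulate_founders(ped, v, seed = 1)
  g <- gene_drop(ped, h, v, seed = 2)

  spec <- data.frame(variant = c("mendel01", "mendel02"),
                     gene = c("GA", "GB"),
                     disease = c("dom_disease", "rec_disease"),
                     mode = c("dominant", "recessive"),
                     effect_class = "test", chrom = "1",
                     pos = c(1e6, 50e6),
                     carriers = c("A1", "B1"), stringsAsFactors = FALSE)
  inj <- inject_mendelian(g, ped, spec, seed = 5)
  tr <- inj$truth

  # carriers obey descent: only pioneer-A descendants can carry mendel01
  fl <- founder_descendant_flags(ped, "A1")
  car1 <- tr$id[tr$variant == "mendel01" & tr$carrier]
  expect_true(all(car1 %in% c("A1", fl$id[fl$in_family])))

  # recessive allele from a single founder: homozygotes only in inbred
  # descendants (B1 contributes through C3 and C4; only E3/G* close a loop)
  hom2 <- tr$id[tr$variant == "mendel02" & tr$homozygote]
  f <- pedigree_inbreeding(additive_relationship(ped))
  expect_true(all(f[hom2] > 0))

  # seeded rerun -> identical placement; non-founder carrier -> error
  inj2 <- inject_mendelian(g, ped, spec, seed = 5)
  expect_identical(inj$truth, inj2$truth)
  spec_bad <- spec; spec_bad$carriers[1] <- "C1"
  expect_error(inject_mendelian(g, ped, spec_bad, seed = 5), "not a founder")

  # injected variants live in the genotype matrix, positions still sorted
  expect_true(all(spec$variant %in% colnames(inj$geno$dosage)))
  expect_s3_class(inj$geno, "geno")
})

test_that("one config and seed reproduce the whole study exactly", {
  cfg <- sim_config(seed = 13, n_target = 80L, n_variants = 200L,
                    n_chrom = 2L, n_blocks = 4L, n_causal_blocks = 2L,
                    n_pleiotropic_blocks = 1L, n_private_blocks_trait2 = 1L)
  s1 <- simulate_study(cfg)
  s2 <- simulate_study(cfg)
  expect_identical(s1$geno$dosage, s2$geno$dosage)
  expect_identical(s1$phenotypes, s2$phenotypes)
  expect_identical(s1$sumstats, s2$sumstats)
  expect_identical(s1$mendelian_truth, s2$mendelian_truth)
})
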