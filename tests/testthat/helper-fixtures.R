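# Hand-built pedigrees, toy genotype constructors, independent oracles, and
# cached simulated studies shared across test files.

ped_trio <- function() {
  validate_pedigree(data.frame(
    id = c("F", "M", "C"), father = c(NA, NA, "F"),
    mother = c(NA, NA, "M"), sex = c("male", "female", "male")))
}

# Two founder couples plus married-in spouses, a first-cousin-like union
# (E3's parents are related through both founder couples) and a
# cross-generation marriage (D1 x founder S3). Expected generations are
# hand-traced longest paths.
ped_toy20 <- function() {
  tab <- rbind(
    data.frame(id = c("A1", "A2", "B1", "B2", "S1", "S2", "S3"),
               father = NA_character_, mother = NA_character_,
               sex = c("male", "female", "male", "female", "female",
                       "male", "female")),
    data.frame(id = c("C1", "C2", "C3", "C4"),
               father = c("A1", "A1", "B1", "B1"),
               mother = c("A2", "A2", "B2", "B2"),
               sex = c("male", "female", "male", "female")),
    data.frame(id = c("D1", "D2", "D3", "D4"),
               father = c("C1", "C1", "C3", "S2"),
               mother = c("C4", "C4", "C2", "C2"),
               sex = c("male", "female", "male", "female")),
    data.frame(id = c("E1", "E2", "E3"),
               father = c("D1", "D1", "D3"),
               mother = c("S3", "S3", "D2"),
               sex = c("male", "female", "male")),
    data.frame(id = c("G1", "G2"), father = "E3", mother = "E2",
               sex = c("male", "female")))
  validate_pedigree(tab)
}

toy20_expected_generation <- c(
  A1 = 0, A2 = 0, B1 = 0, B2 = 0, S1 = 0, S2 = 0, S3 = 0,
  C1 = 1, C2 = 1, C3 = 1, C4 = 1, D1 = 2, D2 = 2, D3 = 2, D4 = 2,
  E1 = 3, E2 = 3, E3 = 3, G1 = 4, G2 = 4)

# child of a full-sib mating: classic f = 0.25
ped_fullsib_child <- function() {
  validate_pedigree(data.frame(
    id = c("F", "M", "S1", "S2", "X"),
    father = c(NA, NA, "F", "F", "S1"),
    mother = c(NA, NA, "M", "M", "S2"),
    sex = c("male", "female", "male", "female", "male")))
}

# Minimal geno object: dosage matrix + evenly spaced variants on one
# chromosome with configurable ref/alt alleles.
make_toy_geno <- function(dosage, ref = NULL, alt = NULL, pos = NULL,
                          chrom = "1", founder_freq = NULL) {
  L <- ncol(dosage)
  if (is.null(colnames(dosage))) colnames(dosage) <- sprintf("v%d", 1:L)
  if (is.null(rownames(dosage)))
    rownames(dosage) <- sprintf("i%d", seq_len(nrow(dosage)))
  if (is.null(ref)) ref <- rep("A", L)
  if (is.null(alt)) alt <- rep("C", L)
  if (is.null(pos)) pos <- seq_len(L) * 1000L
  v <- data.frame(id = colnames(dosage), chrom = chrom, pos = pos,
                  ref = ref, alt = alt, cm = pos / 1e6,
                  stringsAsFactors = FALSE)
  g <- geno_matrix(v, dosage)
  g$founder_freq <- founder_freq
  g
}

# Independent single-locus gene-dropping oracle for the relationship
# matrix: founders carry globally unique allele labels; each meiosis
# transmits one of the parent's two labels with equal probability at each
# of n_loci unlinked loci. The IBD-sharing estimate
#   A_hat[i, j] = mean over loci of (# label matches between i's and j's
#                 two alleles) / 2
# converges to the numerator relationship (diagonal to 1 + f).
drop_labels_oracle <- function(ped, n_loci = 10000) {
  n <- nrow(ped)
  pat <- matrix(0L, n, n_loci)
  mat <- pat
  lab <- 0L
  for (i in order(ped$generation)) {
    if (ped$founder[i]) {
      pat[i, ] <- lab + 1L
      mat[i, ] <- lab + 2L
      lab <- lab + 2L
    } else {
      fi <- match(ped$father[i], ped$id)
      mi <- match(ped$mother[i], ped$id)
      m1 <- stats::runif(n_loci) < 0.5
      m2 <- stats::runif(n_loci) < 0.5
      pat[i, ] <- ifelse(m1, pat[fi, ], mat[fi, ])
      mat[i, ] <- ifelse(m2, pat[mi, ], mat[mi, ])
    }
  }
  Ahat <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (i in seq_len(n)) {
    for (j in i:n) {
      s <- (pat[i, ] == pat[j, ]) + (pat[i, ] == mat[j, ]) +
        (mat[i, ] == pat[j, ]) + (mat[i, ] == mat[j, ])
      Ahat[i, j] <- Ahat[j, i] <- mean(s) / 2
    }
  }
  Ahat
}

# 10 individuals, 3 catalog variants (1 dominant, 2 recessive) and one
# catalog variant absent from the cohort; shared by the Mendelian-calling
# and rule-mining tests.
toy_calls_setup <- function() {
  dosage <- cbind(dom1 = c(0, 1, 2, 0, 0, 1, 0, 0, 0, 0),
                  rec1 = c(0, 1, 1, 2, 0, 0, 1, 0, 2, 0),
                  rec2 = c(0, 0, 0, 0, 0, 0, 0, 0, 0, 1))
  rownames(dosage) <- sprintf("i%02d", 1:10)
  geno <- make_toy_geno(dosage, pos = c(1000L, 2000L, 3000L))
  catalog <- data.frame(
    variant = c("dom1", "rec1", "rec2", "ghost"),
    gene = c("G1", "G2", "G3", "G4"),
    disease = c("dz_dom", "dz_rec", "dz_rec2", "dz_ghost"),
    mode = c("dominant", "recessive", "recessive", "dominant"),
    effect_class = "test", stringsAsFactors = FALSE)
  list(geno = geno, catalog = catalog)
}

# Brute-force rule oracle: double loop over transactions for every
# antecedent/consequent pair.
brute_force_rules <- function(tx, ants, cons) {
  N <- length(tx)
  out <- list()
  for (a in ants) {
    for (cn in cons) {
      nA <- 0L; nC <- 0L; nAC <- 0L
      for (t in tx) {
        hasA <- a %in% t
        hasC <- cn %in% t
        nA <- nA + hasA
        nC <- nC + hasC
        nAC <- nAC + (hasA && hasC)
      }
      if (nA == 0 || nC == 0) next
      out[[paste(a, cn)]] <- c(support = nAC / N, confidence = nAC / nA,
                               lift = (nAC / nA) / (nC / N))
    }
  }
  out
}

# Cached studies (helpers are sourced once per test run).
.study_cache <- new.env(parent = emptyenv())

get_default_study <- function() {
  if (is.null(.study_cache$default))
    .study_cache$default <- simulate_study(sim_config(seed = 7L))
  .study_cache$default
}

get_small_study <- function() {
  if (is.null(.study_cache$small)) {
    .study_cache$small <- simulate_study(
      sim_config(seed = 11L, n_target = 150L, n_variants = 400L,
                 n_blocks = 10L, n_chrom = 2L, n_causal_blocks = 3L,
                 n_pleiotropic_blocks = 2L, n_private_blocks_trait2 = 2L))
  }
  .study_cache$small
}
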