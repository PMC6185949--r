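# Synthetic study generator: pedigree growth, founder haplotypes, gene
# dropping with Haldane recombination, GWAS summary statistics,
# liability-threshold phenotypes, and Mendelian variant injection.
#
# Everything is driven by a single SimulationConfig and a single seed, so
# one (config, seed) pair reproduces the whole study byte for byte.

#' Simulation configuration
#'
#' Collects every knob of the synthetic study. Defaults describe the desk
#' scale the package is validated at: a ~400-member multigenerational
#' pedigree descending from one pioneer couple, 2,000 common variants on 5
#' chromosomes partitioned into 50 LD blocks, a highly heritable liability
#' (`h2 = 0.8`) with a standardized true-score effect of 0.4, and a
#' population prevalence of 0.25 for the broadest phenotype.
#'
#' @param seed base RNG seed; stage seeds are derived from it.
#' @param n_target approximate pedigree size (growth stops at this size).
#' @param n_generations maximum number of descendant generations.
#' @param mean_children mean children per couple (at least one).
#' @param marry_prob probability a child marries and reproduces.
#' @param consang_prob probability a marriage is within-pedigree
#'   (consanguineous), the source of inbreeding loops.
#' @param n_variants number of common variants on the genotyping grid.
#' @param n_chrom number of chromosomes.
#' @param chrom_length_bp chromosome length in bp (map: 1 cM per Mb).
#' @param n_blocks total number of LD blocks (equal-width genome partition).
#' @param af_shape1,af_shape2 Beta parameters of the founder ALT
#'   allele-frequency distribution.
#' @param af_min,af_max clipping bounds for founder frequencies.
#' @param n_causal_blocks number of blocks carrying true effects for the
#'   primary (mood-disorder-like) trait.
#' @param n_pleiotropic_blocks how many of those causal blocks are shared
#'   with the second (lipid-like) trait.
#' @param n_private_blocks_trait2 causal blocks specific to the second trait.
#' @param causal_density probability a variant inside a causal block has a
#'   nonzero effect.
#' @param h2 narrow-sense heritability of the liability, in `[0, 1]`
#'   (1 only for fully deterministic degenerate checks).
#' @param prs_effect standardized liability effect of the true genome-wide
#'   score (`prs_effect^2 <= h2`; the remainder of the genetic variance is a
#'   kinship-structured polygenic background).
#' @param prevalence population prevalence K of the broadest phenotype.
#' @param category_props proportions of BPI / BPII / MDDR / minor diagnostic
#'   categories among affected individuals (must sum to 1).
#' @param gwas_n effective sample size of the external GWAS generating the
#'   summary statistics.
#' @param flip_frac fraction of summary-statistic rows reported with the
#'   REF allele as effect allele (exercises allele harmonisation).
#' @param pioneer_boost risk-allele frequency boost on pioneer haplotypes at
#'   causal loci, creating the in-family enrichment the pedigree was
#'   ascertained for.
#' @return object of class `sim_config` (a validated list).
#' @export
sim_config <- function(seed = 1L,
                       n_target = 400L, n_generations = 6L,
                       mean_children = 3.5, marry_prob = 0.85,
                       consang_prob = 0.08,
                       n_variants = 2000L, n_chrom = 5L,
                       chrom_length_bp = 1e8, n_blocks = 50L,
                       af_shape1 = 1, af_shape2 = 3,
                       af_min = 0.02, af_max = 0.98,
                       n_causal_blocks = 8L, n_pleiotropic_blocks = 4L,
                       n_private_blocks_trait2 = 4L, causal_density = 0.5,
                       h2 = 0.8, prs_effect = 0.4, prevalence = 0.25,
                       category_props = c(BPI = 0.25, BPII = 0.20,
                                          MDDR = 0.25, minor = 0.30),
                       gwas_n = 5e4, flip_frac = 0.5,
                       pioneer_boost = 0.3) {
  stopifnot(h2 >= 0, h2 <= 1, prevalence > 0, prevalence < 1,
            prs_effect^2 <= h2, abs(sum(category_props) - 1) < 1e-8,
            n_blocks %% n_chrom == 0 || n_blocks > n_chrom,
            n_causal_blocks <= n_blocks,
            n_pleiotropic_blocks <= n_causal_blocks)
  cfg <- as.list(environment())
  cfg$seed <- as.integer(seed)
  class(cfg) <- "sim_config"
  cfg
}

.derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 101 + offset) %% .Machine$integer.max)
}

#' Grow a multigenerational pedigree from a pioneer couple
#'
#' Starting from two pioneers, each generation's children marry (mostly
#' married-in founders, occasionally a within-pedigree relative of the same
#' generation) and have Poisson-distributed numbers of children; growth
#' stops near `n_target`. Consanguineous marriages create the inbreeding
#' loops through which recessive founder variants become homozygous.
#'
#' @param config a [sim_config()].
#' @param seed RNG seed (defaults to a stage seed derived from the config).
#' @return a `ped` object with attribute `pioneers` (the two pioneer ids).
#' @export
simulate_pedigree <- function(config, seed = .derive_seed(config$seed, 1L)) {
  set.seed(seed)
  nxt <- local({
    i <- 0L
    function() {
      i <<- i + 1L
      sprintf("ID%04d", i)
    }
  })
  p1 <- nxt(); p2 <- nxt()
  rows <- list(
    data.frame(id = p1, father = NA_character_, mother = NA_character_,
               sex = "male", stringsAsFactors = FALSE),
    data.frame(id = p2, father = NA_character_, mother = NA_character_,
               sex = "female", stringsAsFactors = FALSE))
  n_total <- 2L
  couples <- list(c(father = p1, mother = p2))

  for (g in seq_len(config$n_generations)) {
    children <- list()
    for (cp in couples) {
      if (n_total >= config$n_target) break
      k <- 1L + stats::rpois(1, max(config$mean_children - 1, 0))
      for (j in seq_len(k)) {
        id <- nxt()
        sex <- sample(c("male", "female"), 1)
        rows[[length(rows) + 1L]] <- data.frame(
          id = id, father = cp[["father"]], mother = cp[["mother"]],
          sex = sex, stringsAsFactors = FALSE)
        children[[length(children) + 1L]] <- list(
          id = id, sex = sex, father = cp[["father"]],
          mother = cp[["mother"]])
        n_total <- n_total + 1L
      }
    }
    if (!length(children) || g == config$n_generations) {
      couples <- list()
      next
    }
    married <- rep(FALSE, length(children))
    couples <- list()
    marry_off <- function(i) {
      ch <- children[[i]]
      spouse_id <- NULL
      if (stats::runif(1) < config$consang_prob) {
        cand <- which(!married & seq_along(children) != i &
                        vapply(children, function(o)
                          o$sex != ch$sex && o$father != ch$father,
                          logical(1)))
        if (length(cand)) {
          j <- if (length(cand) == 1) cand else sample(cand, 1)
          spouse_id <- children[[j]]$id
          married[j] <<- TRUE
        }
      }
      if (is.null(spouse_id)) {
        spouse_id <- nxt()
        spouse_sex <- if (ch$sex == "male") "female" else "male"
        rows[[length(rows) + 1L]] <<- data.frame(
          id = spouse_id, father = NA_character_, mother = NA_character_,
          sex = spouse_sex, stringsAsFactors = FALSE)
        n_total <<- n_total + 1L
      }
      married[i] <<- TRUE
      couples[[length(couples) + 1L]] <<-
        if (ch$sex == "male") c(father = ch$id, mother = spouse_id)
        else c(father = spouse_id, mother = ch$id)
    }
    for (i in sample(seq_along(children))) {
      if (married[i] || n_total >= config$n_target) next
      if (stats::runif(1) > config$marry_prob) next
      marry_off(i)
    }
    # keep the lineage alive: at least one couple reproduces per generation
    if (!length(couples) && n_total < config$n_target) marry_off(1L)
  }
  ped <- validate_pedigree(do.call(rbind, rows))
  attr(ped, "pioneers") <- c(p1, p2)
  ped
}

# Variant grid: positions drawn within each chromosome, map 1 cM / Mb.
.simulate_variants <- function(config, seed = .derive_seed(config$seed, 2L)) {
  set.seed(seed)
  per_chrom <- diff(round(seq(0, config$n_variants,
                              length.out = config$n_chrom + 1)))
  bases <- c("A", "C", "G", "T")
  out <- lapply(seq_len(config$n_chrom), function(ch) {
    L <- per_chrom[ch]
    pos <- sort(sample.int(config$chrom_length_bp - 1L, L)) + 1L
    ref <- sample(bases, L, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), "")
    data.frame(chrom = as.character(ch), pos = pos, ref = ref, alt = alt,
               stringsAsFactors = FALSE)
  })
  v <- do.call(rbind, out)
  v$id <- sprintf("var%05d", seq_len(nrow(v)))
  v$cm <- v$pos / 1e6
  v$freq <- pmin(pmax(stats::rbeta(nrow(v), config$af_shape1,
                                   config$af_shape2),
                      config$af_min), config$af_max)
  rownames(v) <- NULL
  v[, c("id", "chrom", "pos", "ref", "alt", "cm", "freq")]
}

#' Equal-width LD-block partition of the simulated genome
#'
#' @param config a [sim_config()].
#' @return data.frame (`block`, `chrom`, `start`, `end`), 0-based half-open
#'   intervals jointly covering every chromosome.
#' @export
make_ld_blocks <- function(config) {
  per_chrom <- diff(round(seq(0, config$n_blocks,
                              length.out = config$n_chrom + 1)))
  rows <- lapply(seq_len(config$n_chrom), function(ch) {
    b <- per_chrom[ch]
    edges <- round(seq(0, config$chrom_length_bp, length.out = b + 1))
    data.frame(chrom = as.character(ch), start = edges[-(b + 1)],
               end = edges[-1], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$block <- sprintf("B%03d", seq_len(nrow(out)))
  rownames(out) <- NULL
  out[, c("block", "chrom", "start", "end")]
}

# True per-variant effects for the primary trait and a second, partially
# pleiotropic trait. Effects are nonzero only inside causal blocks.
.simulate_effects <- function(config, variants, blocks,
                              seed = .derive_seed(config$seed, 3L)) {
  set.seed(seed)
  block_of <- rep(NA_character_, nrow(variants))
  for (k in seq_len(nrow(blocks))) {
    hit <- variants$chrom == blocks$chrom[k] &
      (variants$pos - 1) >= blocks$start[k] &
      (variants$pos - 1) < blocks$end[k]
    block_of[hit] <- blocks$block[k]
  }
  causal1 <- sample(blocks$block, config$n_causal_blocks)
  shared <- causal1[seq_len(config$n_pleiotropic_blocks)]
  private2 <- sample(setdiff(blocks$block, causal1),
                     config$n_private_blocks_trait2)
  causal2 <- c(shared, private2)

  draw <- function(causal_blocks, base = NULL, cor_shared = 0.8) {
    beta <- stats::setNames(numeric(nrow(variants)), variants$id)
    inblk <- block_of %in% causal_blocks
    on <- inblk & stats::runif(nrow(variants)) < config$causal_density
    beta[on] <- stats::rnorm(sum(on))
    if (!is.null(base)) {
      # shared blocks reuse the primary trait's effects with correlated noise
      sh <- block_of %in% shared & base != 0
      beta[sh] <- cor_shared * base[sh] +
        sqrt(1 - cor_shared^2) * stats::rnorm(sum(sh))
    }
    beta
  }
  beta1 <- draw(causal1)
  beta2 <- draw(causal2, base = beta1)
  list(bd = beta1, lipid = beta2, block_of = block_of,
       causal_blocks = list(bd = causal1, lipid = causal2, shared = shared))
}

#' Founder haplotypes
#'
#' Two haplotypes per founder, alleles drawn independently at the configured
#' founder frequencies. Pioneer founders can be enriched for risk alleles at
#' causal loci (`boost`), emulating the elevated polygenic load the study
#' pedigree was ascertained for.
#'
#' @param ped a `ped` object.
#' @param variants variant table with a `freq` column.
#' @param seed RNG seed.
#' @param boost optional list with `ids` (founder ids) and `beta` (named true
#'   effect vector) and `delta` (frequency shift toward the risk allele).
#' @return list with matrices `hap1`, `hap2` (founders x variants, 0/1).
#' @export
simulate_founders <- function(ped, variants, seed, boost = NULL) {
  set.seed(seed)
  fids <- ped$id[ped$founder]
  L <- nrow(variants)
  draw_pair <- function(p) {
    list(stats::rbinom(L, 1, p), stats::rbinom(L, 1, p))
  }
  hap1 <- matrix(0L, length(fids), L, dimnames = list(fids, variants$id))
  hap2 <- hap1
  for (f in fids) {
    p <- variants$freq
    if (!is.null(boost) && f %in% boost$ids) {
      b <- boost$beta[variants$id]
      up <- !is.na(b) & b > 0
      dn <- !is.na(b) & b < 0
      p[up] <- p[up] + boost$delta * (1 - p[up])
      p[dn] <- p[dn] * (1 - boost$delta)
    }
    h <- draw_pair(p)
    hap1[f, ] <- h[[1]]
    hap2[f, ] <- h[[2]]
  }
  list(hap1 = hap1, hap2 = hap2)
}

# One recombined gamete from a parent's two haplotypes. Haldane map:
# switch probability between adjacent loci at genetic distance d Morgans is
# (1 - exp(-2 d)) / 2; the starting haplotype is fair.
.gamete <- function(h1, h2, chrom_idx, rec) {
  out <- integer(length(h1))
  for (c in seq_along(chrom_idx)) {
    ix <- chrom_idx[[c]]
    L <- length(ix)
    phase <- sample(0:1, 1)
    if (L > 1L) {
      sw <- stats::rbinom(L - 1L, 1L, rec[[c]])
      phase <- (phase + c(0L, cumsum(sw))) %% 2L
    }
    out[ix] <- ifelse(phase == 0L, h1[ix], h2[ix])
  }
  out
}

#' Gene dropping down a pedigree
#'
#' Transmits founder haplotypes through the pedigree: every non-founder
#' receives one recombined haplotype from each parent, with crossovers
#' placed by the Haldane (no-interference) map from the variants' cM
#' positions. Returns dosages plus the transmitted haplotypes.
#'
#' @param ped a `ped` object; every non-founder must have both parents.
#' @param founders founder haplotypes from [simulate_founders()].
#' @param variants variant table (`id`, `chrom`, `pos`, `ref`, `alt`, `cm`).
#' @param seed RNG seed.
#' @return a `geno` object (with `haplotypes$pat` / `haplotypes$mat` and
#'   founder allele frequencies filled in).
#' @export
gene_drop <- function(ped, founders, variants, seed) {
  set.seed(seed)
  fids <- ped$id[ped$founder]
  if (!all(fids %in% rownames(founders$hap1)))
    stop("missing founder haplotype for: ",
         paste(setdiff(fids, rownames(founders$hap1)), collapse = ", "))
  n <- nrow(ped)
  L <- nrow(variants)
  chroms <- unique(variants$chrom)
  chrom_idx <- lapply(chroms, function(ch) which(variants$chrom == ch))
  rec <- lapply(chrom_idx, function(ix) {
    d <- diff(variants$cm[ix]) / 100  # Morgans
    0.5 * (1 - exp(-2 * d))
  })
  pat <- matrix(0L, n, L, dimnames = list(ped$id, variants$id))
  mat <- pat
  for (i in order(ped$generation)) {
    id <- ped$id[i]
    if (ped$founder[i]) {
      pat[i, ] <- founders$hap1[id, ]
      mat[i, ] <- founders$hap2[id, ]
      next
    }
    if (is.na(ped$father[i]) || is.na(ped$mother[i]))
      stop("gene_drop requires both parents for non-founder ", id)
    fi <- match(ped$father[i], ped$id)
    mi <- match(ped$mother[i], ped$id)
    pat[i, ] <- .gamete(pat[fi, ], mat[fi, ], chrom_idx, rec)
    mat[i, ] <- .gamete(pat[mi, ], mat[mi, ], chrom_idx, rec)
  }
  dosage <- pat + mat
  g <- geno_matrix(variants, dosage,
                   haplotypes = list(pat = pat, mat = mat))
  g$founder_freq <- founder_allele_freq(g, ped)
  g
}

#' Simulate external GWAS summary statistics
#'
#' Observed effects are the true per-allele effects plus sampling noise with
#' `SE = 1 / sqrt(2 p (1 - p) N)`; two-sided p-values come from the normal
#' reference. A configurable fraction of rows is reported with the REF
#' allele as effect allele (with the sign negated), as real summary files
#' are, so allele harmonisation is exercised.
#'
#' @param variants variant table with `freq`.
#' @param beta_true named vector of true per-allele (ALT) effects.
#' @param gwas_n GWAS sample size.
#' @param seed RNG seed.
#' @param flip_frac fraction reported on the REF allele.
#' @return summary-statistics data.frame (`SNP`, `CHR`, `BP`, `A1`, `A2`,
#'   `BETA`, `SE`, `P`).
#' @export
simulate_summary_stats <- function(variants, beta_true, gwas_n, seed,
                                   flip_frac = 0.5) {
  set.seed(seed)
  p <- variants$freq
  se <- 1 / sqrt(2 * p * (1 - p) * gwas_n)
  beta_hat <- beta_true[variants$id] + stats::rnorm(nrow(variants), 0, se)
  pval <- pmax(2 * stats::pnorm(-abs(beta_hat / se)), 1e-300)
  flip <- stats::runif(nrow(variants)) < flip_frac
  data.frame(SNP = variants$id, CHR = variants$chrom, BP = variants$pos,
             A1 = ifelse(flip, variants$ref, variants$alt),
             A2 = ifelse(flip, variants$alt, variants$ref),
             BETA = unname(ifelse(flip, -beta_hat, beta_hat)),
             SE = se, P = unname(pval), stringsAsFactors = FALSE)
}

#' Liability-threshold phenotypes on a pedigree
#'
#' Liability is `c * PRS_z + a + e` with `a ~ N(0, sigma_a^2 A)` a
#' kinship-structured polygenic background and `e ~ N(0, sigma_e^2)`
#' independent noise, parameterised so the three variance shares sum to one:
#' `c = prs_effect`, `sigma_a^2 = h2 - c^2`, `sigma_e^2 = 1 - h2`.
#' An individual is affected when liability exceeds `qnorm(1 - K)`;
#' affected individuals receive the diagnostic categories BPI, BPII, MDDR
#' and minor by descending liability, so the nested models satisfy
#' narrow (BPI, BPII) within broad (+ MDDR) within broad_extended (all).
#'
#' @param geno a `geno` object (or `NULL` when `prs_effect = 0`).
#' @param kinship numerator relationship matrix or [kinship_eigen()] object.
#' @param config a [sim_config()].
#' @param beta_true named true effect vector used for the true score.
#' @param seed RNG seed.
#' @return data.frame (`id`, `liability`, `affected`, `category`) with
#'   attributes `threshold`, `prs_true` (the standardized true score) and
#'   `h2`.
#' @export
simulate_phenotypes <- function(geno, kinship, config, beta_true,
                                seed = .derive_seed(config$seed, 7L)) {
  ke <- if (inherits(kinship, "kin_eigen")) kinship else kinship_eigen(kinship)
  set.seed(seed)
  n <- length(ke$d)
  cc <- config$prs_effect
  sa2 <- config$h2 - cc^2
  se2 <- 1 - config$h2
  if (cc != 0) {
    b <- beta_true[colnames(geno$dosage)]
    b[is.na(b)] <- 0
    raw <- as.vector(geno$dosage %*% b)
    s <- stats::sd(raw)
    gz <- if (s > 0) (raw - mean(raw)) / s else numeric(n)
  } else gz <- numeric(n)
  a <- if (sa2 > 0)
    sqrt(sa2) * as.vector(ke$U %*% (sqrt(ke$d) * stats::rnorm(n)))
  else numeric(n)
  e <- if (se2 > 0) stats::rnorm(n, 0, sqrt(se2)) else numeric(n)
  liab <- cc * gz + a + e
  tau <- stats::qnorm(1 - config$prevalence)
  aff <- liab > tau

  category <- rep("unaffected", n)
  if (any(aff)) {
    props <- config$category_props
    n_aff <- sum(aff)
    cnt <- diff(round(cumsum(c(0, props)) * n_aff))
    labs <- rep(names(props), cnt)
    ord <- order(liab[aff], decreasing = TRUE)
    category[which(aff)[ord]] <- labs
  }
  ids <- if (!is.null(ke$ids)) ke$ids else
    if (!is.null(geno)) rownames(geno$dosage) else as.character(seq_len(n))
  out <- data.frame(id = ids, liability = liab, affected = as.integer(aff),
                    category = category, stringsAsFactors = FALSE)
  structure(out, threshold = tau, prs_true = gz, h2 = config$h2)
}

#' Binary phenotype under a nested diagnostic model
#'
#' @param pheno phenotype table from [simulate_phenotypes()] or
#'   [load_phenotypes()].
#' @param model one of `"narrow"` (BPI, BPII), `"broad"` (+ MDDR),
#'   `"broad_extended"` (any affected category).
#' @return named 0/1 integer vector, cases = 1.
#' @export
phenotype_model <- function(pheno,
                            model = c("broad_extended", "broad", "narrow")) {
  model <- match.arg(model)
  cases <- switch(model,
                  narrow = c("BPI", "BPII"),
                  broad = c("BPI", "BPII", "MDDR"),
                  broad_extended = c("BPI", "BPII", "MDDR", "minor"))
  stats::setNames(as.integer(pheno$category %in% cases), pheno$id)
}

#' Default Mendelian variant specification
#'
#' Six founder variants at Mendelian disease loci documented in this founder
#' population (familial hypercholesterolemia, sitosterolemia, hereditary
#' hemochromatosis, a cardioprotective LPA splice variant, long-QT syndrome,
#' Ellis-van Creveld syndrome), with founder carriers drawn from the
#' pedigree; pioneer members carry the dominant lipid variant and the
#' recessive Ellis-van Creveld allele, so both segregate widely.
#'
#' @param ped a `ped` object with a `pioneers` attribute.
#' @param config a [sim_config()].
#' @param seed RNG seed.
#' @return data.frame (`variant`, `gene`, `disease`, `mode`, `effect_class`,
#'   `chrom`, `pos`, `carriers` — semicolon-separated founder ids).
#' @export
default_mendelian_spec <- function(ped, config,
                                   seed = .derive_seed(config$seed, 11L)) {
  set.seed(seed)
  pio <- attr(ped, "pioneers")
  founders <- ped$id[ped$founder]
  others <- setdiff(founders, pio)
  pick <- function(k) sample(others, min(k, length(others)))
  spec <- data.frame(
    variant = sprintf("mendel%02d", 1:6),
    gene = c("APOB", "ABCG8", "HFE", "LPA", "KCNH2", "EVC"),
    disease = c("familial_hypercholesterolemia", "sitosterolemia",
                "hemochromatosis", "lpa_deficiency", "long_qt_syndrome",
                "ellis_van_creveld"),
    mode = c("dominant", "recessive", "recessive", "dominant", "dominant",
             "recessive"),
    effect_class = c("damaging_lipid", "damaging_lipid", "iron_overload",
                     "cardioprotective", "cardiac_rhythm",
                     "skeletal_dysplasia"),
    chrom = as.character(rep(seq_len(config$n_chrom), length.out = 6)),
    stringsAsFactors = FALSE)
  spec$pos <- sample.int(config$chrom_length_bp - 10L, 6) + 1L
  carriers <- list(c(pio[1], pick(2)), c(pio[2], pick(3)), pick(4),
                   pick(2), pick(3), c(pio, pick(1)))
  spec$carriers <- vapply(carriers, paste, "", collapse = ";")
  spec
}

#' Inject Mendelian variants into a simulated genotype matrix
#'
#' Each specified variant is placed heterozygously on one random haplotype
#' of its founder carriers and transmitted down the pedigree by single-locus
#' gene dropping (each meiosis passes one of the parent's two alleles with
#' equal probability). Homozygotes for a single-founder recessive allele can
#' therefore only arise in descendants of consanguineous unions. The truth
#' table of resulting carrier states is returned alongside the updated
#' genotypes.
#'
#' @param geno a `geno` object from [gene_drop()] (haplotypes required).
#' @param ped the `ped` object the genotypes were dropped on.
#' @param spec Mendelian specification, see [default_mendelian_spec()].
#' @param seed RNG seed.
#' @return list with `geno` (variants appended, columns re-sorted by
#'   position) and `truth`: long data.frame (`id`, `variant`, `dosage`,
#'   `carrier`, `homozygote`).
#' @export
inject_mendelian <- function(geno, ped, spec, seed) {
  stopifnot(inherits(geno, "geno"), !is.null(geno$haplotypes))
  set.seed(seed)
  n <- nrow(ped)
  founders <- ped$id[ped$founder]
  pat_new <- matrix(0L, n, nrow(spec), dimnames = list(ped$id, spec$variant))
  mat_new <- pat_new
  for (k in seq_len(nrow(spec))) {
    carriers <- strsplit(spec$carriers[k], ";", fixed = TRUE)[[1]]
    bad <- setdiff(carriers, founders)
    if (length(bad))
      stop("carrier id not a founder: ", paste(bad, collapse = ", "))
    for (f in carriers) {
      if (sample(0:1, 1) == 0) pat_new[f, k] <- 1L else mat_new[f, k] <- 1L
    }
    for (i in order(ped$generation)) {
      if (ped$founder[i]) next
      fi <- match(ped$father[i], ped$id)
      mi <- match(ped$mother[i], ped$id)
      pat_new[i, k] <- if (sample(0:1, 1) == 0) pat_new[fi, k]
                       else mat_new[fi, k]
      mat_new[i, k] <- if (sample(0:1, 1) == 0) pat_new[mi, k]
                       else mat_new[mi, k]
    }
  }
  dos_new <- pat_new + mat_new
  truth <- data.frame(
    id = rep(ped$id, nrow(spec)),
    variant = rep(spec$variant, each = n),
    dosage = as.vector(dos_new),
    stringsAsFactors = FALSE)
  truth$carrier <- truth$dosage >= 1
  truth$homozygote <- truth$dosage == 2

  v_new <- data.frame(id = spec$variant, chrom = spec$chrom, pos = spec$pos,
                      ref = "G", alt = "A", cm = spec$pos / 1e6,
                      freq = NA_real_, stringsAsFactors = FALSE)
  variants <- rbind(geno$variants[, names(v_new)], v_new)
  ord <- order(as.character(variants$chrom), variants$pos)
  variants <- variants[ord, , drop = FALSE]
  rownames(variants) <- NULL
  dosage <- cbind(geno$dosage, dos_new)[, variants$id, drop = FALSE]
  haps <- list(pat = cbind(geno$haplotypes$pat, pat_new)[, variants$id],
               mat = cbind(geno$haplotypes$mat, mat_new)[, variants$id])
  g2 <- geno_matrix(variants, dosage, haplotypes = haps)
  g2$founder_freq <- founder_allele_freq(g2, ped)
  list(geno = g2, truth = truth)
}

#' Simulate a complete synthetic study
#'
#' Runs every generator stage from a single configuration: pedigree, variant
#' grid and LD blocks, true effects for the primary trait and a partially
#' pleiotropic second trait, pioneer-boosted founder haplotypes, gene drop,
#' Mendelian variant injection, liability-threshold phenotypes, and external
#' GWAS summary statistics for both traits.
#'
#' @param config a [sim_config()].
#' @return list with `config`, `ped`, `geno`, `A` (relationship matrix),
#'   `blocks`, `sumstats` (list per trait), `catalog` (Mendelian catalog as
#'   consumed by [call_mendelian_status()]), `mendelian_truth`,
#'   `phenotypes`, and `truth` (true effects, causal blocks, true score).
#' @export
simulate_study <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  ped <- simulate_pedigree(config)
  variants <- .simulate_variants(config)
  blocks <- make_ld_blocks(config)
  eff <- .simulate_effects(config, variants, blocks)
  founders <- simulate_founders(
    ped, variants, seed = .derive_seed(config$seed, 4L),
    boost = list(ids = attr(ped, "pioneers"), beta = eff$bd,
                 delta = config$pioneer_boost))
  geno <- gene_drop(ped, founders, variants,
                    seed = .derive_seed(config$seed, 5L))
  spec <- default_mendelian_spec(ped, config)
  inj <- inject_mendelian(geno, ped, spec,
                          seed = .derive_seed(config$seed, 6L))
  A <- additive_relationship(ped)
  ke <- kinship_eigen(A)
  pheno <- simulate_phenotypes(inj$geno, ke, config, eff$bd)
  sumstats <- list(
    bd = simulate_summary_stats(variants, eff$bd, config$gwas_n,
                                seed = .derive_seed(config$seed, 8L),
                                flip_frac = config$flip_frac),
    lipid = simulate_summary_stats(variants, eff$lipid, config$gwas_n,
                                   seed = .derive_seed(config$seed, 9L),
                                   flip_frac = config$flip_frac))
  list(config = config, ped = ped, geno = inj$geno, A = A, kin_eigen = ke,
       blocks = blocks, sumstats = sumstats,
       catalog = spec[, c("variant", "gene", "disease", "mode",
                          "effect_class", "chrom", "pos")],
       mendelian_truth = inj$truth, phenotypes = pheno,
       truth = list(beta_true = eff[c("bd", "lipid")],
                    causal_blocks = eff$causal_blocks,
                    prs_true = attr(pheno, "prs_true")))
}
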